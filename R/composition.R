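## Composition tables keyed by lipid descriptor (chain length : double
## bonds per chain), cholesterol fraction and temperature, and the pairwise
## trend statistics built on them.  Pair discovery is rule-based on the
## descriptors, not hard-coded to any particular lipid set.

#' Parse a lipid chain descriptor
#'
#' Descriptors follow the `"C1:U1,C2:U2"` convention, e.g. `"18:1,18:1"`
#' for a di-C18 lipid with one double bond per chain.
#'
#' @param chains character vector of descriptors.
#' @return a data frame with columns `c1`, `u1`, `c2`, `u2` (chains sorted
#'   so that `(c1, u1) <= (c2, u2)`), `carbons` (total) and `bonds` (total).
#' @export
#' @examples
#' parse_chains("18:0,18:1")
parse_chains <- function(chains) {
  parts <- strsplit(chains, ",", fixed = TRUE)
  one <- function(p) {
    if (length(p) != 2) stop("descriptor must have two chains", call. = FALSE)
    m <- do.call(rbind, lapply(p, function(s) {
      cu <- suppressWarnings(
        as.integer(strsplit(trimws(s), ":", fixed = TRUE)[[1]]))
      if (length(cu) != 2 || anyNA(cu)) {
        stop("bad chain descriptor: ", s, call. = FALSE)
      }
      cu
    }))
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    c(c1 = m[1, 1], u1 = m[1, 2], c2 = m[2, 1], u2 = m[2, 2])
  }
  out <- as.data.frame(do.call(rbind, lapply(parts, one)))
  out$carbons <- out$c1 + out$c2
  out$bonds <- out$u1 + out$u2
  out
}

#' Composition table constructor
#'
#' @param lipid lipid names.
#' @param chains chain descriptors (see [parse_chains()]); may be `NA` for
#'   rows not entering chain-based statistics.
#' @param chol_percent cholesterol mole percent.
#' @param T temperature (K).
#' @param mu_m membrane shear viscosity (mPa s); `NA` allowed for excluded
#'   rows.
#' @param excluded manual exclusion flag (e.g. gel-phase systems).
#' @return a data frame of class `composition_table`.
#' @export
composition_table <- function(lipid, chains = NA_character_,
                              chol_percent = 0, T, mu_m, excluded = FALSE) {
  df <- data.frame(lipid = lipid, chains = chains,
                   chol_percent = chol_percent, T = T, mu_m = mu_m,
                   excluded = excluded)
  key <- paste(df$lipid, df$chol_percent, df$T)
  if (anyDuplicated(key)) stop("duplicate composition rows", call. = FALSE)
  if (any(!is.na(df$mu_m) & df$mu_m <= 0)) {
    stop("viscosities must be positive", call. = FALSE)
  }
  structure(df, class = c("composition_table", "data.frame"))
}

## usable rows with parsed chains, same T and cholesterol level
.chain_rows <- function(table) {
  df <- as.data.frame(table)
  df <- df[!df$excluded & !is.na(df$mu_m) & !is.na(df$chains), , drop = FALSE]
  if (nrow(df) == 0) return(df)
  cbind(df, parse_chains(df$chains))
}

#' Viscosity increment per two-carbon chain elongation
#'
#' Finds all pairs of table rows (at equal temperature and cholesterol
#' content) whose chain descriptors are identical except that both chains
#' of one lipid are longer by two carbons at the same unsaturation pattern,
#' and returns the pairwise viscosity differences (longer minus shorter).
#'
#' @param table a [composition_table()].
#' @return an object of class `increment_stats`: list with `pairs` (data
#'   frame: shorter, longer, delta), `mean`, `sd` (sample, `n - 1`) and
#'   `per` = "two-carbon elongation step".
#' @export
elongation_increments <- function(table) {
  df <- .chain_rows(table)
  pairs <- list()
  if (nrow(df) > 1) {
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        if (i == j) next
        a <- df[i, ]; b <- df[j, ]
        if (a$T != b$T || a$chol_percent != b$chol_percent) next
        if (b$c1 == a$c1 + 2 && b$c2 == a$c2 + 2 &&
            b$u1 == a$u1 && b$u2 == a$u2) {
          pairs[[length(pairs) + 1]] <- data.frame(
            shorter = a$lipid, longer = b$lipid, delta = b$mu_m - a$mu_m)
        }
      }
    }
  }
  if (length(pairs) == 0) {
    stop("no two-carbon elongation pair found in the table", call. = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  structure(list(pairs = pairs, mean = mean(pairs$delta),
                 sd = if (nrow(pairs) > 1) stats::sd(pairs$delta) else 0,
                 per = "two-carbon elongation step (one CH2 pair per chain)"),
            class = "increment_stats")
}

#' Viscosity decrement per chain double bond
#'
#' Finds all pairs of rows (equal temperature, cholesterol and chain
#' lengths) differing only in the number of double bonds and returns the
#' per-double-bond viscosity decrements
#' `(mu_fewer_bonds - mu_more_bonds) / delta_bonds`.
#'
#' @param table a [composition_table()].
#' @param exclusions lipid names left out of the pairing (e.g. outliers).
#' @return an `increment_stats` object (`pairs` has columns `saturated_end`,
#'   `unsaturated_end`, `delta_bonds`, `decrement`).
#' @export
unsaturation_increments <- function(table, exclusions = character(0)) {
  df <- .chain_rows(table)
  df <- df[!df$lipid %in% exclusions, , drop = FALSE]
  pairs <- list()
  if (nrow(df) > 1) {
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        a <- df[i, ]; b <- df[j, ]
        if (a$T != b$T || a$chol_percent != b$chol_percent) next
        if (a$c1 == b$c1 && a$c2 == b$c2 && b$bonds > a$bonds) {
          pairs[[length(pairs) + 1]] <- data.frame(
            saturated_end = a$lipid, unsaturated_end = b$lipid,
            delta_bonds = b$bonds - a$bonds,
            decrement = (a$mu_m - b$mu_m) / (b$bonds - a$bonds))
        }
      }
    }
  }
  if (length(pairs) == 0) {
    stop("no unsaturation pair found in the table", call. = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  structure(list(pairs = pairs, mean = mean(pairs$decrement),
                 sd = if (nrow(pairs) > 1) stats::sd(pairs$decrement) else 0,
                 per = "double bond"),
            class = "increment_stats")
}

#' @export
print.increment_stats <- function(x, ...) {
  cat(sprintf("Viscosity increment per %s: %.2f +/- %.2f mPa.s (%d pairs)\n",
              x$per, x$mean, x$sd, nrow(x$pairs)))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero at a printed precision
#'
#' Report-string rounding convention; raw values are always kept alongside.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
#' @examples
#' round_half_away(3.35, 1)  # 3.4
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## ---- packaged reference tables --------------------------------------------

#' Packaged all-atom viscosity table
#'
#' The shipped table of membrane shear viscosities of all-atom
#' phosphatidylcholine bilayers by acyl-chain composition, cholesterol
#' content and temperature (sets AA-1..AA-4; the gel-phase DSPC row is
#' flagged excluded with no viscosity).
#'
#' @return a [composition_table()] with an additional `set` column.
#' @export
aa_viscosity_table <- function() {
  path <- system.file("extdata", "aa_viscosity_table.csv",
                      package = "memvisc", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- composition_table(
    lipid = df$system, chains = ifelse(df$chains == "", NA, df$chains),
    chol_percent = df$chol_percent, T = df$T_K,
    mu_m = df$mu_m_mPas, excluded = df$excluded)
  tab$set <- df$set
  tab
}

#' Packaged DOPC viscosity-vs-temperature series
#'
#' The pure-DOPC rows of [aa_viscosity_table()] across all simulated
#' temperatures (293-333 K; the 333 K bilayer is shared between the
#' chain-composition and temperature sets).
#'
#' @return a [thermal_series()] of kind `"viscosity"`.
#' @export
dopc_temperature_series <- function() {
  tab <- aa_viscosity_table()
  sel <- !is.na(tab$chains) & tab$chains == "18:1,18:1" &
    tab$chol_percent == 0 & !tab$excluded
  thermal_series(T = tab$T[sel], value = tab$mu_m[sel],
                 kind = "viscosity", label = "DOPC")
}

#' Packaged coarse-grained route viscosities
#'
#' The shipped table of membrane shear viscosities of the coarse-grained
#' DPPC bilayer at 315 K extracted by the different inference routes.
#'
#' @return data frame with columns `system`, `route`, `mu_m`, `uncertainty`.
#' @export
cg_route_table <- function() {
  path <- system.file("extdata", "cg_route_viscosities.csv",
                      package = "memvisc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
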