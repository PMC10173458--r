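## Trajectory ensembles: per-probe in-plane positions (wrapped or unwrapped)
## and a continuous in-plane orientation angle, on a uniform time grid.
## Interchange format: TSV with columns
##   frame, time_ns, probe_id, x_nm, y_nm, theta_rad, leaflet, label
## plus a JSON sidecar holding the membrane-system metadata and wrapped flag.

#' Trajectory ensemble container
#'
#' @param times frame times in ns, uniformly spaced (relative tolerance
#'   1e-6).
#' @param x,y numeric matrices, frames x probes, in-plane coordinates (nm).
#' @param theta optional numeric matrix, frames x probes, cumulative
#'   rotation angle about the membrane normal (rad, continuous, never
#'   reduced mod 2*pi).
#' @param wrapped logical; if `TRUE` all coordinates must lie in `[0, L)`.
#' @param L box edge (nm); scalar or per-frame vector.
#' @param probe_labels,leaflet_labels optional per-probe tags.
#' @return an object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(times, x, y, theta = NULL, wrapped = FALSE,
                                L = NA_real_, probe_labels = NULL,
                                leaflet_labels = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(length(times) == nrow(x), all(dim(x) == dim(y)))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1]))) {
      stop("trajectory times must be uniformly spaced", call. = FALSE)
    }
  }
  if (!is.null(theta)) {
    theta <- as.matrix(theta)
    stopifnot(all(dim(theta) == dim(x)))
    if (nrow(theta) > 1 && any(abs(diff(theta)) >= pi)) {
      stop("orientation angles must be continuous (|dtheta| < pi per frame)",
           call. = FALSE)
    }
  }
  if (isTRUE(wrapped)) {
    if (!all(is.finite(L)) || any(L <= 0)) {
      stop("a wrapped trajectory requires a positive box edge L", call. = FALSE)
    }
    Lf <- rep_len(L, nrow(x))
    if (any(x < 0) || any(y < 0) || any(x >= Lf) || any(y >= Lf)) {
      stop("wrapped coordinates must lie in [0, L) in every frame",
           call. = FALSE)
    }
  }
  n <- ncol(x)
  structure(list(times = as.numeric(times), x = x, y = y, theta = theta,
                 wrapped = isTRUE(wrapped), L = L,
                 probe_labels = probe_labels %||% rep("probe", n),
                 leaflet_labels = leaflet_labels),
            class = "trajectory_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trajectory ensemble: %d probes, %d frames, dt = %g ns, %s%s\n",
    ncol(x$x), nrow(x$x),
    if (length(x$times) > 1) x$times[2] - x$times[1] else NA,
    if (x$wrapped) "wrapped" else "unwrapped",
    if (is.null(x$theta)) "" else ", with orientations"))
  invisible(x)
}

#' Unwrap box-wrapped lateral coordinates
#'
#' Reconstructs continuous paths from wrapped coordinates by minimum-image
#' displacement accumulation, assuming true per-frame displacements smaller
#' than `L/2` in magnitude.  Re-wrapping the result reproduces the input
#' exactly.
#'
#' @param traj a wrapped [trajectory_ensemble()].
#' @return an unwrapped `trajectory_ensemble`.  If the box edge varies
#'   between frames by more than `L/2` a warning reports the number of
#'   suspect steps.
#' @export
unwrap_lateral <- function(traj) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (!traj$wrapped) stop("trajectory is not wrapped", call. = FALSE)
  Lf <- rep_len(traj$L, nrow(traj$x))
  if (length(unique(Lf)) > 1) {
    suspect <- sum(abs(diff(Lf)) > Lf[-length(Lf)] / 2)
    if (suspect > 0) {
      warning(sprintf(
        "%d frame-to-frame box changes exceed L/2; unwrapping may be wrong",
        suspect), call. = FALSE)
    }
  }
  unwrap_mat <- function(m) {
    if (nrow(m) == 1) return(m)
    d <- diff(m)
    d <- d - round(sweep(d, 1, Lf[-1], "/")) * Lf[-1]
    out <- apply(rbind(m[1, , drop = FALSE], d), 2, cumsum)
    matrix(out, nrow = nrow(m))
  }
  out <- traj
  out$x <- unwrap_mat(traj$x)
  out$y <- unwrap_mat(traj$y)
  out$wrapped <- FALSE
  out
}

#' Wrap continuous lateral coordinates into the periodic box
#'
#' Inverse of [unwrap_lateral()] up to the choice of image: coordinates are
#' reduced into `[0, L)`.
#'
#' @param traj an unwrapped [trajectory_ensemble()] with a valid box edge.
#' @param L optional box edge override (nm).
#' @return a wrapped `trajectory_ensemble`.
#' @export
wrap_lateral <- function(traj, L = traj$L) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (traj$wrapped) stop("trajectory is already wrapped", call. = FALSE)
  .check_positive(L = L[1])
  Lf <- rep_len(L, nrow(traj$x))
  wrap_mat <- function(m) {
    m <- m - floor(sweep(m, 1, Lf, "/")) * Lf
    m[m >= Lf] <- 0   # guard against round-up to exactly L
    m
  }
  out <- traj
  out$x <- wrap_mat(traj$x)
  out$y <- wrap_mat(traj$y)
  out$wrapped <- TRUE
  out$L <- L
  out
}

#' Write / read a trajectory ensemble in the interchange format
#'
#' The trajectory is stored as a TSV file (`frame`, `time_ns`, `probe_id`,
#' `x_nm`, `y_nm`, `theta_rad`, `leaflet`, `label`) with a JSON sidecar
#' (`<path>.json`) holding the wrapped flag, box edge and any membrane-system
#' metadata.
#'
#' @param traj a [trajectory_ensemble()].
#' @param path TSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param metadata optional named list merged into the sidecar (e.g.
#'   membrane-system fields).
#' @return `write_trajectory()`: `path` invisibly; `read_trajectory()`: a
#'   `trajectory_ensemble` with a `metadata` attribute.
#' @export
write_trajectory <- function(traj, path, metadata = list()) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  nf <- nrow(traj$x); np <- ncol(traj$x)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, np),
    time_ns = rep(traj$times, np),
    probe_id = rep(seq_len(np), each = nf),
    x_nm = as.vector(traj$x),
    y_nm = as.vector(traj$y),
    theta_rad = if (is.null(traj$theta)) NA_real_ else as.vector(traj$theta),
    leaflet = if (is.null(traj$leaflet_labels)) NA_character_ else
      rep(traj$leaflet_labels, each = nf),
    label = rep(traj$probe_labels, each = nf)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(wrapped = traj$wrapped, L_nm = traj$L), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- sort(unique(df$probe_id))
  df <- df[order(df$probe_id, df$frame), ]
  nf <- length(unique(df$frame))
  as_mat <- function(v) matrix(v, nrow = nf, ncol = length(ids))
  theta <- if (all(is.na(df$theta_rad))) NULL else as_mat(df$theta_rad)
  traj <- trajectory_ensemble(
    times = df$time_ns[df$probe_id == ids[1]],
    x = as_mat(df$x_nm), y = as_mat(df$y_nm), theta = theta,
    wrapped = isTRUE(side$wrapped), L = side$L_nm %||% NA_real_,
    probe_labels = df$label[match(ids, df$probe_id)],
    leaflet_labels = if (all(is.na(df$leaflet))) NULL else
      df$leaflet[match(ids, df$probe_id)]
  )
  attr(traj, "metadata") <- side
  traj
}
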