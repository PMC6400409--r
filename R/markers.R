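#' Marker trajectory set
#'
#' Lab-frame trajectories of the optical markers of the tracking clusters,
#' on one shared uniform time base. Each cluster is an M x 3 x N array
#' (markers x coordinates x frames), mm.
#'
#' @param times Uniformly spaced times, s.
#' @param clusters Named list of M x 3 x N arrays.
#' @return An object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(times, clusters) {
  times <- as.numeric(times)
  stopifnot(is.list(clusters), length(clusters) >= 1L, !is.null(names(clusters)))
  for (nm in names(clusters)) {
    a <- clusters[[nm]]
    if (length(dim(a)) != 3L || dim(a)[2L] != 3L || dim(a)[3L] != length(times)) {
      stop(sprintf("cluster '%s' must be an M x 3 x %d array", nm, length(times)),
           call. = FALSE)
    }
    if (anyNA(a)) {
      stop(sprintf("cluster '%s' has missing frames; gaps are not interpolated", nm),
           call. = FALSE)
    }
  }
  structure(list(times = times, clusters = clusters), class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("Marker trajectories: %d frames, clusters: %s\n", length(x$times),
              paste(sprintf("%s (%d markers)", names(x$clusters),
                            vapply(x$clusters, function(a) dim(a)[1L], 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Synthesize noisy marker trajectories from a pose series
#'
#' Emulates optical tracking of two rigid marker clusters: the fixed-bone
#' cluster is stationary in the lab frame (the fixed bone defines the global
#' frame), the moving-bone cluster follows the pose series. Isotropic i.i.d.
#' Gaussian noise of standard deviation `sigma` is added to every marker
#' coordinate at every frame; the same seed reproduces the same output.
#'
#' @param poses A `pose_series` for the moving bone.
#' @param geom_fixed,geom_moving `cluster_geometry` marker offsets (body
#'   frames), mm.
#' @param sigma Marker noise SD per coordinate, mm (>= 0).
#' @param seed Integer RNG seed.
#' @return A `marker_trajectories` with clusters `"fixed"` and `"moving"`.
#' @export
make_marker_trajectories <- function(poses, geom_fixed, geom_moving,
                                     sigma = 0.012, seed = 1L) {
  stopifnot(inherits(poses, "pose_series"))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  geom_fixed <- cluster_geometry(geom_fixed)
  geom_moving <- cluster_geometry(geom_moving)
  N <- length(poses$times)
  fixed <- array(rep(t(unclass(geom_fixed)), N),
                 c(3L, nrow(geom_fixed), N))
  fixed <- aperm(fixed, c(2L, 1L, 3L))
  moving <- array(0, c(nrow(geom_moving), 3L, N))
  for (m in seq_len(nrow(geom_moving))) {
    p <- geom_moving[m, ]
    moving[m, , ] <- apply_rotations(poses$rotations, p) + t(poses$origins)
  }
  if (sigma > 0) {
    withr::with_seed(as.integer(seed), {
      fixed <- fixed + array(stats::rnorm(length(fixed), 0, sigma), dim(fixed))
      moving <- moving + array(stats::rnorm(length(moving), 0, sigma), dim(moving))
    })
  }
  dimnames(fixed) <- list(rownames(geom_fixed), c("x", "y", "z"), NULL)
  dimnames(moving) <- list(rownames(geom_moving), c("x", "y", "z"), NULL)
  marker_trajectories(poses$times, list(fixed = fixed, moving = moving))
}

#' Write marker trajectories to a TRC file
#'
#' Tab-delimited TRC (Track Row Column) motion-capture format with the
#' standard two header rows (DataRate/CameraRate/NumFrames/NumMarkers,
#' Units = mm) followed by `Frame#`, `Time` and X/Y/Z columns per marker.
#' All clusters are concatenated; marker names are prefixed with the
#' cluster name (`fixed_m1`, ...).
#'
#' @param markers A `marker_trajectories`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path) {
  times <- markers$times
  rate <- if (length(times) > 1L) 1 / diff(times[1:2]) else 100
  names_all <- character(0)
  cols <- list()
  for (nm in names(markers$clusters)) {
    a <- markers$clusters[[nm]]
    mk <- dimnames(a)[[1L]]
    if (is.null(mk)) mk <- paste0("m", seq_len(dim(a)[1L]))
    for (m in seq_len(dim(a)[1L])) {
      names_all <- c(names_all, paste0(nm, "_", mk[m]))
      cols[[length(cols) + 1L]] <- t(a[m, , ])
    }
  }
  nmark <- length(names_all)
  nfr <- length(times)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", rate, rate, nfr, nmark, rate, nfr),
    paste(c("Frame#", "Time", as.vector(rbind(names_all, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), nmark),
                           rep(seq_len(nmark), each = 3L))), collapse = "\t"),
    ""
  ), con)
  dat <- do.call(cbind, cols)
  tab <- cbind(seq_len(nfr), times, dat)
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' Reads the TRC dialect written by [write_trc()]. Marker names of the form
#' `<cluster>_<marker>` are split back into clusters; unprefixed markers go
#' into a single cluster `"markers"`.
#'
#' @param path TRC file path.
#' @return A `marker_trajectories`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[4L], "\t")[[1L]]
  marker_names <- hdr[seq(3L, length(hdr), by = 3L)]
  marker_names <- marker_names[nzchar(marker_names)]
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  dat <- utils::read.table(text = body, sep = "\t", header = FALSE)
  times <- as.numeric(dat[[2L]])
  nfr <- nrow(dat)
  split_names <- regmatches(marker_names, regexpr("_", marker_names), invert = TRUE)
  cl_of <- vapply(split_names, function(p) if (length(p) == 2L) p[1L] else "markers", "")
  mk_of <- vapply(split_names, function(p) if (length(p) == 2L) p[2L] else p[1L], "")
  clusters <- list()
  for (cl in unique(cl_of)) {
    idx <- which(cl_of == cl)
    a <- array(0, c(length(idx), 3L, nfr),
               dimnames = list(mk_of[idx], c("x", "y", "z"), NULL))
    for (j in seq_along(idx)) {
      col0 <- 2L + (idx[j] - 1L) * 3L
      a[j, , ] <- t(as.matrix(dat[, col0 + 1:3]))
    }
    clusters[[cl]] <- a
  }
  marker_trajectories(times, clusters)
}

#' Write marker trajectories as plain CSV
#'
#' Columns: `time`, then `<cluster>_<marker>_x/_y/_z` for every marker.
#'
#' @param markers A `marker_trajectories`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  out <- data.frame(time = markers$times)
  for (nm in names(markers$clusters)) {
    a <- markers$clusters[[nm]]
    mk <- dimnames(a)[[1L]]
    for (m in seq_len(dim(a)[1L])) {
      for (k in 1:3) {
        out[[paste0(nm, "_", mk[m], "_", c("x", "y", "z")[k])]] <- a[m, k, ]
      }
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read marker trajectories from the CSV dialect of [write_marker_csv()]
#'
#' @param path CSV file path.
#' @return A `marker_trajectories`.
#' @export
read_marker_csv <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time" %in% names(dat))
  times <- dat$time
  cols <- setdiff(names(dat), "time")
  m <- regmatches(cols, regexec("^([^_]+)_(.+)_([xyz])$", cols))
  ok <- lengths(m) == 4L
  if (!all(ok)) stop("unrecognized marker column names", call. = FALSE)
  info <- do.call(rbind, lapply(m, function(p) p[2:4]))
  clusters <- list()
  for (cl in unique(info[, 1L])) {
    mk <- unique(info[info[, 1L] == cl, 2L])
    a <- array(0, c(length(mk), 3L, length(times)),
               dimnames = list(mk, c("x", "y", "z"), NULL))
    for (j in seq_along(mk)) {
      for (k in 1:3) {
        a[j, k, ] <- dat[[paste0(cl, "_", mk[j], "_", c("x", "y", "z")[k])]]
      }
    }
    clusters[[cl]] <- a
  }
  marker_trajectories(times, clusters)
}
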