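#' Wall-motion grid of one ultrasound segmentation
#'
#' A `motion_grid` stores the speckle-tracked material-point trajectories of
#' one segmentation of a 4D ultrasound acquisition: a structured surface grid
#' of `n` rings ("heights") along the vessel with `m` circumferential points
#' each (36 for the tracking export this package emulates), followed over `T`
#' frames of one cardiac cycle.  Frame 1 is the end-diastolic reference
#' configuration.
#'
#' @param positions numeric array of dimension `c(T, n, m, 3)` with Cartesian
#'   coordinates in mm.
#' @param frame_times optional numeric vector of `T` frame times in seconds.
#' @param patient_id,segmentation_id optional identifiers carried through the
#'   pipeline.
#' @return an object of class `motion_grid`.
#' @seealso [read_motion_grid()], [trim_pseudo_apex()], [build_quad_mesh()]
#' @export
motion_grid <- function(positions, frame_times = NULL, patient_id = NA_character_,
                        segmentation_id = NA_character_) {
  if (!is.array(positions) || length(dim(positions)) != 4L || dim(positions)[4] != 3L)
    stop("`positions` must be a (frames x heights x circumferential x 3) array")
  g <- structure(
    list(positions = positions, frame_times = frame_times,
         patient_id = patient_id, segmentation_id = segmentation_id),
    class = "motion_grid")
  validate_motion_grid(g)
  g
}

validate_motion_grid <- function(g) {
  d <- dim(g$positions)
  if (d[1] < 2L) stop("a motion grid needs at least 2 frames")
  if (d[2] < 2L || d[2] > 36L) stop("number of heights must be in [2, 36]")
  if (d[3] < 3L) stop("need at least 3 circumferential points")
  if (!all(is.finite(g$positions))) stop("non-finite coordinate in motion grid")
  if (!is.null(g$frame_times) && length(g$frame_times) != d[1])
    stop("frame_times length must equal the number of frames")
  invisible(g)
}

#' @export
print.motion_grid <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<motion_grid> %d frames, %d heights x %d circumferential points\n",
              d[1], d[2], d[3]))
  if (!is.na(x$patient_id)) cat("  patient:     ", x$patient_id, "\n")
  if (!is.na(x$segmentation_id)) cat("  segmentation:", x$segmentation_id, "\n")
  invisible(x)
}

#' @rdname motion_grid
#' @param x a `motion_grid`.
#' @export
n_frames <- function(x) dim(x$positions)[1]

#' @rdname motion_grid
#' @export
n_heights <- function(x) dim(x$positions)[2]

#' @rdname motion_grid
#' @export
n_circ <- function(x) dim(x$positions)[3]

#' Node coordinates of one frame
#'
#' Returns the node positions of one frame as an `(n*m) x 3` matrix whose
#' row order matches the mesh node ids: node id `(i-1)*m + j` for height `i`
#' and circumferential index `j` (1-based).
#'
#' @param grid a [motion_grid()].
#' @param frame 1-based frame index.
#' @return numeric matrix (nodes x 3), mm.
#' @export
frame_nodes <- function(grid, frame) {
  d <- dim(grid$positions)
  mat <- matrix(aperm(grid$positions[frame, , , , drop = FALSE],
                      c(3, 2, 4, 1)), ncol = 3)
  ## aperm above yields j fastest, then i: row (i-1)*m + j
  mat
}

#' Read a wall-motion grid from a delimited table
#'
#' Parses the tracking export format: a delimited text file with header
#' `frame,i,j,x,y,z`, one row per (frame, node), 0-based `frame`, `i`, `j`
#' indices and coordinates in mm.  Every (frame, i, j) triple must be present
#' exactly once.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; `""` (default) auto-detects comma vs. tab.
#' @param patient_id,segmentation_id identifiers attached to the result.
#' @return a [motion_grid()].
#' @export
read_motion_grid <- function(path, sep = "", patient_id = NA_character_,
                             segmentation_id = NA_character_) {
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- read.csv(path, sep = sep, header = TRUE)
  need <- c("frame", "i", "j", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("motion grid table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(tab[, need]))))
    stop("non-finite value in motion grid table ", path)
  tt <- max(tab$frame) + 1L
  nn <- max(tab$i) + 1L
  mm <- max(tab$j) + 1L
  if (nrow(tab) != tt * nn * mm || anyDuplicated(tab[, c("frame", "i", "j")])) {
    ## report the first absent triple
    want <- expand.grid(j = 0:(mm - 1), i = 0:(nn - 1), frame = 0:(tt - 1))
    key <- paste(want$frame, want$i, want$j)
    have <- paste(tab$frame, tab$i, tab$j)
    miss <- setdiff(key, have)
    if (length(miss))
      stop("motion grid table is missing cell (frame,i,j) = (",
           gsub(" ", ",", miss[1]), ")")
    stop("duplicated (frame,i,j) rows in motion grid table")
  }
  pos <- array(NA_real_, c(tt, nn, mm, 3))
  idx <- cbind(tab$frame + 1L, tab$i + 1L, tab$j + 1L)
  pos[cbind(idx, 1L)] <- tab$x
  pos[cbind(idx, 2L)] <- tab$y
  pos[cbind(idx, 3L)] <- tab$z
  motion_grid(pos, patient_id = patient_id, segmentation_id = segmentation_id)
}

#' Write a wall-motion grid to a delimited table
#'
#' Inverse of [read_motion_grid()]; numbers are written with full double
#' precision so a read/write round trip is exact.
#'
#' @param grid a [motion_grid()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_motion_grid <- function(grid, path, sep = ",") {
  d <- dim(grid$positions)
  g <- expand.grid(j = 0:(d[3] - 1), i = 0:(d[2] - 1), frame = 0:(d[1] - 1))
  idx <- cbind(g$frame + 1L, g$i + 1L, g$j + 1L)
  tab <- data.frame(frame = g$frame, i = g$i, j = g$j,
                    x = grid$positions[cbind(idx, 1L)],
                    y = grid$positions[cbind(idx, 2L)],
                    z = grid$positions[cbind(idx, 3L)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = sep), con)
  body <- apply(cbind(format(tab[, 1:3], trim = TRUE, scientific = FALSE),
                      format(tab[, 4:6], trim = TRUE, digits = 17)),
                1L, paste, collapse = sep)
  writeLines(body, con)
  invisible(path)
}

#' Remove the pseudo-apex rings from a motion grid
#'
#' The tracking software closes the masked wall region with an artificial cap
#' (the pseudo-apex) whose rings carry no wall-motion information.  This drops
#' a contiguous run of height indices at one or both ends of the grid.
#'
#' @param grid a [motion_grid()].
#' @param drop_rows integer vector of 1-based height indices to remove; must
#'   be contiguous runs attached to the first and/or last height.
#' @return the trimmed [motion_grid()] (frame count unchanged).
#' @export
trim_pseudo_apex <- function(grid, drop_rows) {
  n <- n_heights(grid)
  drop_rows <- sort(unique(as.integer(drop_rows)))
  if (length(drop_rows) == 0L) return(grid)
  if (any(drop_rows < 1L | drop_rows > n)) stop("drop_rows out of range")
  keep <- setdiff(seq_len(n), drop_rows)
  if (length(keep) < 2L) stop("fewer than 2 heights would remain")
  ## kept rows must themselves be one contiguous block, i.e. drops only at ends
  if (any(diff(keep) != 1L))
    stop("drop_rows must be contiguous runs at the ends of the height range")
  motion_grid(grid$positions[, keep, , , drop = FALSE],
              frame_times = grid$frame_times, patient_id = grid$patient_id,
              segmentation_id = grid$segmentation_id)
}
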