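#' Labelled 3D point cloud
#'
#' Thin container for the CT-derived wall and calcification clouds and for
#' ultrasound geometry exported as points.  Coordinates are in mm.
#'
#' @param points numeric matrix (points x 3).
#' @param label one of `"wall"`, `"calcification"`, `"ultrasound"`.
#' @return object of class `point_cloud` (a matrix with a `label` attribute).
#' @export
point_cloud <- function(points, label = c("wall", "calcification", "ultrasound")) {
  label <- match.arg(label)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("point cloud must have 3 columns")
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(points))) stop("non-finite coordinate in point cloud")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, label = label, class = c("point_cloud", class(points)))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, label '%s'\n", nrow(x), attr(x, "label")))
  invisible(x)
}

#' Read / write XYZ and ASCII-PLY point files
#'
#' `read_point_cloud()` accepts plain whitespace-delimited XYZ text (three
#' numeric columns, optional comment lines starting with `#`) and ASCII PLY
#' files with at least `x y z` vertex properties.  `write_point_cloud()`
#' writes XYZ, or ASCII PLY when the path ends in `.ply`.
#'
#' @param path file path; format chosen by extension (`.ply` vs. anything
#'   else).
#' @param label cloud label, see [point_cloud()].
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, label = "wall") {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
    if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
    endh <- which(lines == "end_header")[1]
    ev <- grep("^element vertex", lines[1:endh], value = TRUE)[1]
    nv <- as.integer(strsplit(trimws(ev), "\\s+")[[1]][3])
    props <- grep("^property", lines[1:endh], value = TRUE)
    pnames <- vapply(strsplit(trimws(props), "\\s+"), function(x) x[3], "")
    ix <- match(c("x", "y", "z"), pnames)
    if (any(is.na(ix))) stop("PLY vertex element lacks x/y/z properties")
    body <- lines[(endh + 1):(endh + nv)]
    vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    point_cloud(vals[, ix, drop = FALSE], label)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    vals <- do.call(rbind, lapply(strsplit(trimws(lines), "[,[:space:]]+"),
                                  as.numeric))
    if (ncol(vals) < 3L) stop("XYZ file must have at least 3 columns")
    point_cloud(vals[, 1:3, drop = FALSE], label)
  }
}

#' @rdname read_point_cloud
#' @param cloud a [point_cloud()] (or plain matrix).
#' @export
write_point_cloud <- function(cloud, path) {
  pts <- as.matrix(cloud)
  txt <- apply(format(pts, trim = TRUE, digits = 17), 1L, paste, collapse = " ")
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(pts)),
                "property double x", "property double y", "property double z",
                "end_header")
    writeLines(c(header, txt), path)
  } else {
    writeLines(txt, path)
  }
  invisible(path)
}
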