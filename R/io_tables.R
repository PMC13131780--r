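# Particle coordinate tables.
#
# Plain CSV with header `class_id,x,y,z`. Coordinates are 0-based floating
# voxel coordinates in x,y,z column order; class_id >= 1 for particles
# (0 is reserved for background).

#' Create a particle table
#'
#' @param class_id integer vector of class ids (>= 1 for particles).
#' @param x,y,z numeric 0-based voxel coordinates.
#' @return A data.frame with columns `class_id`, `x`, `y`, `z`.
#' @export
particle_table <- function(class_id = integer(), x = numeric(),
                           y = numeric(), z = numeric()) {
  tab <- data.frame(class_id = as.integer(class_id),
                    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  validate_particles(tab)
}

validate_particles <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (!identical(names(tab)[1:4], c("class_id", "x", "y", "z")))
    stop("particle table must have columns class_id, x, y, z")
  if (nrow(tab) > 0) {
    if (any(!is.finite(as.matrix(tab[c("x", "y", "z")]))))
      stop("particle coordinates must be finite")
    if (any(tab$class_id < 1L))
      stop("particle class_id must be >= 1 (0 is background)")
  }
  tab
}

#' Read a particle coordinate table
#'
#' @param path CSV file with header `class_id,x,y,z`.
#' @return A particle table data.frame.
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("particle table not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "class_id,x,y,z")
    stop("malformed particle table header in ", path,
         " (expected 'class_id,x,y,z')")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(particle_table())
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L, " in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 4, byrow = TRUE)
  badnum <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(badnum) > 0)
    stop("non-numeric field at line ", badnum[1] + 1L, " in ", path)
  particle_table(class_id = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4])
}

#' Write a particle coordinate table
#'
#' @param tab particle table data.frame.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_particles <- function(tab, path) {
  tab <- validate_particles(tab)
  lines <- c("class_id,x,y,z",
             if (nrow(tab) > 0)
               sprintf("%d,%s,%s,%s", tab$class_id,
                       format(tab$x, digits = 17, trim = TRUE, scientific = FALSE),
                       format(tab$y, digits = 17, trim = TRUE, scientific = FALSE),
                       format(tab$z, digits = 17, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
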