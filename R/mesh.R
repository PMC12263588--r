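# Triangulated-surface utilities shared by the sac generator, the coil tube
# sweep and the wall-index maps. Meshes are plain lists:
#   vertices: n x 3 matrix (m); faces: m x 3 integer matrix (1-based, CCW
#   outward).

#' @keywords internal
new_trimesh <- function(vertices, faces) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  list(vertices = vertices, faces = matrix(as.integer(faces), ncol = 3))
}

#' Signed volume of a closed triangulated surface
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; positive
#' for consistently outward-oriented faces.
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @return volume in the cube of the vertex unit.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Per-triangle areas of a mesh
#' @inheritParams mesh_volume
#' @return numeric vector, one area per face.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Barycentric node area weights
#'
#' Lumps each triangle's area equally onto its three vertices, so the
#' weights sum to the total surface area. Used to turn per-node index maps
#' into area fractions.
#'
#' @inheritParams mesh_volume
#' @return numeric vector of per-vertex areas (m^2).
#' @export
node_area_weights <- function(mesh) {
  ta <- triangle_areas(mesh)
  w <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    s <- tapply(rep(ta / 3, 1), mesh$faces[, k], sum)
    w[as.integer(names(s))] <- w[as.integer(names(s))] + as.numeric(s)
  }
  w
}

#' Watertightness check
#'
#' A closed orientable surface has every undirected edge shared by exactly
#' two faces, traversed once in each direction.
#'
#' @inheritParams mesh_volume
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key_dir)) return(FALSE)   # non-manifold / flipped face
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(table(key_und) == 2L)
}

# Icosahedron subdivided n times, vertices projected to the unit sphere.
#' @keywords internal
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mids <- new.env(parent = emptyenv())
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      id <- mids[[k]]
      if (!is.null(id)) return(id)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1]] <<- p
      id <- n + length(newv)
      assign(k, id, envir = mids)
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c_, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  new_trimesh(v, f)
}

#' Write a mesh as ASCII STL
#' @inheritParams mesh_volume
#' @param path output file path.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "hemocoil") {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nrm^2))
  nn[nn == 0] <- 1
  nrm <- nrm / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- paste0(
    "facet normal %.9g %.9g %.9g\n outer loop\n",
    "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
    "  vertex %.9g %.9g %.9g\n endloop\nendfacet")
  lines <- sprintf(fmt,
                   nrm[, 1], nrm[, 2], nrm[, 3],
                   v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
                   v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
                   v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(lines, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path file written by [write_ply()] or any ASCII PLY with
#'   triangular faces.
#' @return a mesh list (`vertices`, `faces`).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  start <- which(lines == "end_header")
  vl <- lines[(start + 1):(start + nv)]
  fl <- lines[(start + nv + 1):(start + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
  f <- do.call(rbind, lapply(strsplit(fl, " "),
                             function(x) as.integer(x[2:4]) + 1L))
  new_trimesh(v, f)
}
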