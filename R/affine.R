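#' 12-parameter affine spatial transforms
#'
#' An `affine_transform` is a world-mm to world-mm mapping parameterised by
#' 3 translations (mm), 3 rotations (deg, applied as Rz Ry Rx), 3 scales and
#' 3 shears, with rotation/scale/shear taken about an explicit `center`
#' (mm). This is the "deformation field" of each step of the alignment
#' chain; transforms compose, invert and serialise to JSON.
#'
#' @param translation,rotation,scale,shear numeric length-3 blocks of the
#'   12 parameters (deg for rotation).
#' @param center rotation/scale centre in world mm.
#' @param source_space,target_space optional space labels used to validate
#'   chains (e.g. `"allen200" -> "waxholm"`).
#' @return An object of class `affine_transform` with fields `matrix`
#'   (4x4 homogeneous), `params` (named 12-vector) and `center`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0),
                             center = c(0, 0, 0),
                             source_space = NULL, target_space = NULL) {
  p <- c(translation, rotation, scale, shear)
  if (length(p) != 12L || any(!is.finite(p))) stop("need 12 finite parameters")
  names(p) <- param_names()
  m <- params_to_matrix(p, center)
  if (det(m[1:3, 1:3]) <= 0) stop("affine must have positive determinant")
  structure(list(matrix = m, params = p, center = as.numeric(center),
                 source_space = source_space, target_space = target_space),
            class = "affine_transform")
}

param_names <- function() {
  c("tx", "ty", "tz", "rx", "ry", "rz", "sx", "sy", "sz",
    "hxy", "hxz", "hyz")
}

#' @export
print.affine_transform <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<affine_transform> t=(%.3g, %.3g, %.3g) mm  ",
                     "r=(%.3g, %.3g, %.3g) deg\n  s=(%.4g, %.4g, %.4g)  ",
                     "shear=(%.3g, %.3g, %.3g)\n"),
              p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8], p[9],
              p[10], p[11], p[12]))
  if (!is.null(x$source_space))
    cat(sprintf("  %s -> %s\n", x$source_space, x$target_space))
  invisible(x)
}

rot3 <- function(deg) {
  r <- deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# params (named 12-vector) -> 4x4 homogeneous world matrix
params_to_matrix <- function(p, center = c(0, 0, 0)) {
  sh <- diag(3)
  sh[1, 2] <- p[10]; sh[1, 3] <- p[11]; sh[2, 3] <- p[12]
  a3 <- rot3(p[4:6]) %*% sh %*% diag(p[7:9], 3)
  m <- diag(4)
  m[1:3, 1:3] <- a3
  m[1:3, 4] <- p[1:3] + center - a3 %*% center
  m
}

# 4x4 matrix (+ center) -> named 12-vector; requires positive determinant
matrix_to_params <- function(m, center = c(0, 0, 0)) {
  a <- m[1:3, 1:3]
  if (det(a) <= 0) stop("cannot decompose: non-positive determinant")
  qrd <- qr(a)
  q <- qr.Q(qrd); r <- qr.R(qrd)
  s <- sign(diag(r)); s[s == 0] <- 1
  q <- q %*% diag(s); r <- diag(s) %*% r
  if (det(q) < 0) { q <- -q; r <- -r }       # det(a) > 0 keeps diag(r) > 0
  sc <- diag(r)
  sh <- c(r[1, 2] / sc[2], r[1, 3] / sc[3], r[2, 3] / sc[3])
  ry <- asin(max(-1, min(1, -q[3, 1])))
  rx <- atan2(q[3, 2], q[3, 3])
  rz <- atan2(q[2, 1], q[1, 1])
  tr <- m[1:3, 4] - center + a %*% center
  p <- c(tr, c(rx, ry, rz) * 180 / pi, sc, sh)
  names(p) <- param_names()
  p
}

#' Build an affine_transform from a 4x4 matrix
#' @param m 4x4 homogeneous matrix with positive-determinant linear part.
#' @param center rotation centre used when decomposing into parameters.
#' @inheritParams affine_transform
#' @export
affine_from_matrix <- function(m, center = c(0, 0, 0),
                               source_space = NULL, target_space = NULL) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4)) || abs(det(m)) < .Machine$double.eps)
    stop("matrix must be invertible 4x4")
  p <- matrix_to_params(m, center)
  structure(list(matrix = m, params = p, center = as.numeric(center),
                 source_space = source_space, target_space = target_space),
            class = "affine_transform")
}

#' Invert an affine transform
#' @param t an `affine_transform`.
#' @export
invert_transform <- function(t) {
  affine_from_matrix(solve(t$matrix), center = t$center,
                     source_space = t$target_space,
                     target_space = t$source_space)
}

#' Apply a transform to world points
#' @param t an `affine_transform`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(t, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(t$matrix %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Ordered chain of affine transforms
#'
#' The saved per-step alignments (e.g. allen200 -> allen25 -> grayNissl ->
#' waxholm) kept as an explicit ordered chain: the first element is applied
#' first. Adjacent space labels, when present, must match.
#'
#' @param ... `affine_transform` objects, or a single list of them.
#' @export
transform_chain <- function(...) {
  links <- list(...)
  if (length(links) == 1L && is.list(links[[1]]) &&
      !inherits(links[[1]], "affine_transform"))
    links <- links[[1]]
  if (!length(links)) stop("empty chain")
  for (i in seq_along(links))
    if (!inherits(links[[i]], "affine_transform"))
      stop("chain element ", i, " is not an affine_transform")
  for (i in seq_len(length(links) - 1L)) {
    a <- links[[i]]$target_space; b <- links[[i + 1L]]$source_space
    if (!is.null(a) && !is.null(b) && !identical(a, b))
      stop(sprintf("space label mismatch in chain: '%s' -> '%s'", a, b))
  }
  structure(list(links = links), class = "transform_chain")
}

#' Compose a transform chain into one affine
#'
#' Multiplies the chain into a single matrix in application order (first
#' link applied first), so energy maps can be moved into the final space
#' with a single interpolation pass instead of repeated regridding.
#'
#' @param chain a [transform_chain] or list of `affine_transform`s.
#' @return A single `affine_transform`.
#' @export
compose_chain <- function(chain) {
  if (inherits(chain, "transform_chain")) chain <- chain$links
  if (inherits(chain, "affine_transform")) chain <- list(chain)
  chain <- transform_chain(chain)$links
  m <- diag(4)
  for (l in chain) m <- l$matrix %*% m
  affine_from_matrix(m, center = chain[[1]]$center,
                     source_space = chain[[1]]$source_space,
                     target_space = chain[[length(chain)]]$target_space)
}

#' Serialize / deserialize a transform as JSON
#'
#' Transforms are stored as `{source_space, target_space, matrix
#' (row-major 16 floats), params (12 floats), center}`.
#'
#' @param t an `affine_transform`.
#' @param path output / input file path.
#' @export
write_transform <- function(t, path) {
  obj <- list(source_space = t$source_space, target_space = t$target_space,
              matrix = as.numeric(t(t$matrix)),
              params = as.numeric(t$params), center = t$center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(obj$matrix, 4, 4, byrow = TRUE)
  affine_from_matrix(m, center = obj$center,
                     source_space = obj$source_space,
                     target_space = obj$target_space)
}
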