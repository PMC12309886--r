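#' Diffusion direction sets
#'
#' A direction set is a matrix of unit 3-vectors with a label and a flag
#' marking closure under negation (antipodal sets allow experimental
#' cross-term correction by averaging opposite polarities).
#'
#' @param vectors n x 3 matrix of directions (rows are normalized).
#' @param label short name.
#' @return an object of class `direction_set`.
#' @export
direction_set <- function(vectors, label = "custom") {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 3)
  nrm <- sqrt(rowSums(vectors^2))
  stopifnot(all(nrm > 0))
  vectors <- vectors / nrm
  colnames(vectors) <- c("x", "y", "z")
  antipodal <- all(apply(vectors, 1, function(v)
    any(colSums(abs(t(vectors) + v)) < 1e-9)))
  structure(list(label = label, vectors = vectors, antipodal = antipodal),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("direction set '%s': %d unit vectors%s\n", x$label,
              nrow(x$vectors), if (x$antipodal) " (antipodal)" else ""))
  invisible(x)
}

#' Well-distributed directions by electrostatic repulsion
#'
#' Generates `n` unit vectors approximately minimizing the Coulomb energy of
#' point charges on the sphere. Initialization is seeded and the iteration
#' budget fixed, so the output is deterministic given `(n, seed, iterations)`.
#' For n = 6 the converged set is an octahedron (the cardinal axes up to a
#' global rotation).
#'
#' @param n number of directions (>= 1).
#' @param seed RNG seed for the initial configuration.
#' @param iterations fixed iteration budget.
#' @return a `direction_set`.
#' @examples
#' d <- well_distributed(30, seed = 1)
#' range(sqrt(rowSums(d$vectors^2)))
#' @export
well_distributed <- function(n, seed = 1L, iterations = 2000L) {
  stopifnot(n >= 1)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  X <- matrix(rnorm(3 * n), n, 3)
  X <- X / sqrt(rowSums(X^2))
  if (n == 1)
    return(direction_set(X, label = sprintf("repulsion-%d", n)))
  # Coulomb energy of unit charges; gradient projected on the sphere tangent
  fn <- function(x) {
    U <- matrix(x, n, 3)
    U <- U / sqrt(rowSums(U^2))
    D <- as.matrix(stats::dist(U))
    sum(1 / D[upper.tri(D)])
  }
  gr <- function(x) {
    U <- matrix(x, n, 3)
    r <- sqrt(rowSums(U^2))
    U <- U / r
    G <- matrix(0, n, 3)
    D2 <- as.matrix(stats::dist(U))^2
    diag(D2) <- Inf
    W <- D2^-1.5
    for (k in 1:3) {
      Dk <- outer(U[, k], U[, k], "-")
      G[, k] <- -rowSums(Dk * W)
    }
    G <- (G - U * rowSums(G * U)) / r
    as.vector(G)
  }
  opt <- stats::optim(as.vector(X), fn, gr, method = "BFGS",
                      control = list(maxit = iterations, reltol = 1e-14))
  U <- matrix(opt$par, n, 3)
  U <- U / sqrt(rowSums(U^2))
  direction_set(U, label = sprintf("repulsion-%d", n))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cardinal direction sets
#'
#' The standard three-directional set (x, y, z) and the six-directional
#' antipodal set (x, y, z, -x, -y, -z) used for experimental cross-term
#' correction.
#'
#' @return a list with `direction_set` elements `xyz` and `xyz_antipodal`.
#' @export
cardinal_sets <- function() {
  I3 <- diag(3)
  list(xyz = direction_set(I3, "xyz"),
       xyz_antipodal = direction_set(rbind(I3, -I3), "xyz-antipodal"))
}

#' Directional signal averaging
#'
#' Averages signals across diffusion encoding directions, per b-value, using
#' either the geometric or the arithmetic mean.
#'
#' @param signals numeric matrix, rows = b-values, columns = directions (a
#'   vector is treated as one row).
#' @param scheme `"geometric"` or `"arithmetic"`.
#' @return vector of averaged signals, one per row.
#' @export
directional_average <- function(signals, scheme = c("geometric", "arithmetic")) {
  scheme <- match.arg(scheme)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (scheme == "geometric") {
    if (any(signals <= 0))
      stop("geometric averaging requires strictly positive signals")
    exp(rowMeans(log(signals)))
  } else {
    rowMeans(signals)
  }
}

#' Read/write direction tables
#'
#' Plain-text three-column unit-vector files, one direction per line (the
#' de-facto gradient-table convention).
#'
#' @param path file path.
#' @param dirs a `direction_set` (for writing).
#' @param label label for the set read from file.
#' @return `read_directions` returns a `direction_set`; `write_directions`
#'   returns `path` invisibly.
#' @export
read_directions <- function(path, label = basename(path)) {
  m <- as.matrix(read.table(path))
  direction_set(m, label = label)
}

#' @rdname read_directions
#' @export
write_directions <- function(dirs, path) {
  write.table(format(dirs$vectors, digits = 15), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
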