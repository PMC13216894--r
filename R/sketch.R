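#' Bottom-s MinHash sketch of a genome
#'
#' Hashes every canonical k-mer (k-mers containing N are skipped) with a
#' seeded 64-bit hash truncated to 53 bits - so sketch values are exactly
#' representable as doubles - and keeps the s smallest distinct values.
#'
#' @param genome DNAStringSet or named character vector.
#' @param k k-mer size (default 21).
#' @param s sketch size (default 500000 hashes).
#' @param seed hash seed; sketches are only comparable at equal seeds
#'   (default 42).
#' @param label genome label carried into distance matrices.
#' @return object of class `minhash_sketch` with strictly increasing
#'   `values`.
#' @export
minhash_sketch <- function(genome, k = 21, s = 500000, seed = 42,
                           label = "genome") {
  genome <- as_genome_chr(genome)
  values <- cpp_sketch(unname(genome), as.integer(k), as.numeric(s),
                       as.integer(seed))
  structure(list(k = as.integer(k), s = as.numeric(s),
                 seed = as.integer(seed), label = label, values = values),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("minhash_sketch '", x$label, "': k=", x$k, ", s=", format(x$s),
      ", ", length(x$values), " values\n", sep = "")
  invisible(x)
}

#' Write / read a sketch as a sorted value list with a JSON header line
#'
#' Values are 53-bit hashes, written as exact decimal integers.
#'
#' @param sketch a `minhash_sketch`.
#' @param path file path.
#' @return invisibly, `path` (writer) or the sketch (reader).
#' @export
write_sketch <- function(sketch, path) {
  hdr <- jsonlite::toJSON(sketch[c("k", "s", "seed", "label")],
                          auto_unbox = TRUE)
  writeLines(c(as.character(hdr), sprintf("%.0f", sketch$values)), path)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  structure(list(k = hdr$k, s = hdr$s, seed = hdr$seed, label = hdr$label,
                 values = as.numeric(lines[-1])), class = "minhash_sketch")
}

check_sketch_compat <- function(s1, s2) {
  if (s1$k != s2$k || s1$s != s2$s || s1$seed != s2$seed)
    stop("sketches have mismatched parameters (k/s/seed)")
}

#' Mash distance between two sketches
#'
#' Jaccard similarity j is estimated from the bottom-s values of the merged
#' union (the merged-sketch estimator); the distance is
#' `D = -(1/k) * log(2j / (1+j))`, 0 when j = 1 and capped at 1 when j = 0.
#' Whole-genome similarity is `1 - D`.
#'
#' @param s1,s2 `minhash_sketch` objects with equal k, s and seed.
#' @return list with `distance`, `similarity`, `jaccard`, `shared` (shared
#'   hashes among the bottom-s union) and `denominator`.
#' @export
mash_distance <- function(s1, s2) {
  check_sketch_compat(s1, s2)
  u <- sort(unique(c(s1$values, s2$values)))
  denom <- min(s1$s, length(u))
  u <- u[seq_len(denom)]
  shared <- sum(u %in% s1$values & u %in% s2$values)
  j <- if (denom > 0) shared / denom else 0
  d <- if (j <= 0) 1 else min(1, -log(2 * j / (1 + j)) / s1$k)
  list(distance = d, similarity = 1 - d, jaccard = j, shared = shared,
       denominator = denom)
}

#' Pairwise Mash distance and similarity matrices
#'
#' @param sketches list of `minhash_sketch` objects with matching parameters
#'   and unique labels.
#' @return object of class `mash_matrix`: symmetric zero-diagonal `distance`
#'   matrix, `similarity = 1 - distance`, and `shared` hash counts, labelled
#'   in input order.
#' @export
mash_distance_matrix <- function(sketches) {
  stopifnot(length(sketches) >= 2)
  labels <- vapply(sketches, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate sketch labels")
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sh <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- mash_distance(sketches[[i]], sketches[[j]])
    d[i, j] <- d[j, i] <- m$distance
    sh[i, j] <- sh[j, i] <- m$shared
  }
  structure(list(distance = d, similarity = 1 - d, shared = sh,
                 labels = labels), class = "mash_matrix")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Double-centers the squared distances, `B = -0.5 * J %*% D^2 %*% J` with
#' centering matrix `J = I - 1/n`, and eigendecomposes B.  Axes with positive
#' eigenvalues are retained; coordinates are eigenvectors scaled by the
#' square roots of their eigenvalues, and variance explained is each positive
#' eigenvalue over the positive-eigenvalue total.  Negative eigenvalues are
#' reported but excluded from the coordinates.
#'
#' @param d a `mash_matrix` or a symmetric zero-diagonal distance matrix.
#' @return object of class `pcoa_result`: `points` (rows = labels),
#'   `eigenvalues` (descending), `variance_explained` per retained axis, and
#'   `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  if (inherits(d, "mash_matrix")) d <- d$distance
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  n <- nrow(d)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-9 + 1e-12
  pos <- e$values > tol
  coords <- if (any(pos)) {
    e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), nrow = sum(pos))
  } else matrix(0, n, 0)
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    points = coords,
    eigenvalues = e$values,
    variance_explained = if (any(pos)) e$values[pos] / sum(e$values[pos])
      else numeric(0),
    negative_eigenvalues = e$values[e$values < -tol]),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  ve <- paste(sprintf("%.1f%%", 100 * head(x$variance_explained, 3)),
              collapse = ", ")
  cat("pcoa_result:", nrow(x$points), "points,", ncol(x$points),
      "axes (variance explained:", ve, ")\n")
  invisible(x)
}
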