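## Geometric conceptual spaces.
##
## Symbols are seed points in a Euclidean space; classification assigns a
## query to the symbol whose (possibly modulated, possibly gapped)
## half-spaces all contain it.  For each seed pair (s, s') the separating
## hyperplane is perpendicular to their connecting segment; expectation
## modulation shifts it from the midpoint towards the less likely symbol
## by alpha * (p(s) - p(s')) / (p(s) + p(s')) * (|s - s'| / 2), and a gap
## g shrinks every region by g/2 per side, leaving an explicit GAP zone.

#' Symbol returned for points falling in a gap zone
#' @export
GAP <- "GAP"

#' Create a conceptual space
#'
#' @param dimension dimensionality of the space (fixed at creation).
#' @param gap gap width `g >= 0` between regions (distance units).
#' @param alpha expectation-modulation strength (dimensionless, >= 0).
#' @param entropyScaling if `TRUE`, the effective alpha is scaled by
#'   `1 - H(D)/log2(|A|)` so that sharper (more informative) expectation
#'   distributions move boundaries more.
#' @param weights optional per-dimension distance weights.
#' @param tol discriminability tolerance of [addSeed()]: a point within
#'   `tol` of an existing seed is that seed.
#' @return a [ConceptualSpace-class].
#' @export
ConceptualSpace <- function(dimension, gap = 0, alpha = 0.5,
                            entropyScaling = FALSE, weights = NULL,
                            tol = 1e-6) {
  stopifnot(dimension >= 1, gap >= 0, alpha >= 0, is.finite(gap),
            is.finite(alpha))
  if (is.null(weights)) weights <- rep(1, dimension)
  stopifnot(length(weights) == dimension, all(weights > 0))
  e <- new.env(parent = emptyenv())
  e$dim <- as.integer(dimension)
  e$seeds <- matrix(numeric(0), 0, dimension)
  e$symbols <- character(0)
  e$gap <- gap; e$alpha <- alpha; e$entropyScaling <- entropyScaling
  e$weights <- weights; e$tol <- tol
  new("ConceptualSpace", env = e)
}

#' @rdname spaceSymbols
#' @export
spaceDimension <- function(space) space@env$dim

#' Space accessors
#'
#' @param space a [ConceptualSpace-class].
#' @return `spaceSymbols`: the symbols (alphabet order); `seedPoints`: the
#'   seed matrix (one row per symbol); `spaceDimension`: dimensionality.
#' @export
spaceSymbols <- function(space) space@env$symbols

#' @rdname spaceSymbols
#' @export
seedPoints <- function(space) {
  m <- space@env$seeds
  rownames(m) <- space@env$symbols
  m
}

.spaceDist <- function(e, a, b) sqrt(sum(e$weights * (a - b)^2))

#' Add a seed point, minting a symbol
#'
#' A point within the discriminability tolerance of an existing seed
#' returns that seed's symbol unchanged; otherwise a new symbol is minted
#' and appended to the alphabet.  Points landing in a gap region of the
#' current tessellation are exactly the ones for which [classifyPoint()]
#' returns `GAP`; adding them as seeds is how new symbols arise.
#'
#' @param space a [ConceptualSpace-class].
#' @param point numeric vector of the space's dimensionality.
#' @param symbol optional symbol name (default auto-minted).
#' @return the symbol labelling the point.
#' @export
addSeed <- function(space, point, symbol = NULL) {
  e <- space@env
  point <- as.numeric(point)
  if (length(point) != e$dim)
    stop("point dimensionality mismatch", call. = FALSE)
  if (nrow(e$seeds)) {
    d <- sqrt(colSums(e$weights * (t(e$seeds) - point)^2))
    hit <- which(d <= e$tol)
    if (length(hit)) return(e$symbols[hit[1]])
  }
  if (is.null(symbol)) symbol <- paste0("s", nrow(e$seeds) + 1L)
  e$seeds <- rbind(e$seeds, point)
  e$symbols <- c(e$symbols, symbol)
  symbol
}

#' Classify a point under expectation-modulated, gapped Voronoi regions
#'
#' @param space a [ConceptualSpace-class].
#' @param q query point.
#' @param D optional expectation distribution over the space's symbols
#'   (named numeric, non-negative, summing to 1); uniform if absent.
#' @return the symbol whose region contains `q`, or [GAP].  With
#'   `gap = 0` and `alpha = 0` this is exactly nearest-seed
#'   classification; boundary ties resolve to the lowest symbol index.
#' @export
classifyPoint <- function(space, q, D = NULL) {
  e <- space@env
  q <- as.numeric(q)
  if (length(q) != e$dim) stop("point dimensionality mismatch", call. = FALSE)
  n <- nrow(e$seeds)
  if (n == 0L) return(GAP)
  if (n == 1L) return(e$symbols[1])
  if (is.null(D)) {
    p <- stats::setNames(rep(1 / n, n), e$symbols)
  } else {
    if (is.null(names(D)) || !all(e$symbols %in% names(D)))
      stop("D must cover the space's symbols", call. = FALSE)
    p <- D[e$symbols]
  }
  alpha <- e$alpha
  if (e$entropyScaling && n > 1) {
    H <- entropyBits(p / sum(p))
    alpha <- alpha * (1 - H / log2(n))
  }
  ws <- e$weights
  margins <- rep(Inf, n)
  for (s in seq_len(n)) {
    for (s2 in seq_len(n)) {
      if (s2 == s) next
      xs <- e$seeds[s, ]; x2 <- e$seeds[s2, ]
      L <- sqrt(sum(ws * (xs - x2)^2))
      if (L == 0) next
      u <- (xs - x2) / L                       # unit vector towards s
      m <- (xs + x2) / 2
      denom <- p[s] + p[s2]
      delta <- if (denom > 0)
        alpha * (p[s] - p[s2]) / denom * (L / 2) else 0
      b <- m - delta * u                       # plane moves away from s
                                               # when s is the likelier
      margin <- sum(ws * (q - b) * u)
      margins[s] <- min(margins[s], margin)
    }
  }
  eligible <- which(margins >= e$gap / 2 - 1e-12)
  if (!length(eligible)) return(GAP)
  e$symbols[eligible[which.max(margins[eligible])]]
}

#' Spectrally abstract a trajectory into a single point
#'
#' Resamples the trajectory (piecewise-constant in time, weighted by the
#' per-point durations) to a fixed number of samples, applies a discrete
#' cosine transform per dimension and concatenates the magnitudes of the
#' first `k` coefficients.  The result is invariant to uniform time
#' dilation, so the same shape traversed slower maps to the same point.
#'
#' @param points matrix (one row per trajectory point) or numeric vector
#'   (1-d trajectory).
#' @param k number of spectral coefficients kept per dimension.
#' @param durations per-point durations (default equal).
#' @param resampleN number of resample points.
#' @return numeric vector of length `k * ncol(points)`.
#' @export
abstractTrajectory <- function(points, k = 8, durations = NULL,
                               resampleN = 32) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  m <- nrow(points)
  if (m == 0L) stop("empty trajectory", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(durations)) durations <- rep(1, m)
  stopifnot(length(durations) == m, all(durations > 0))
  edges <- cumsum(durations)
  total <- edges[m]
  tq <- (seq_len(resampleN) - 0.5) / resampleN * total
  idx <- findInterval(tq, edges) + 1L
  idx[idx > m] <- m
  X <- points[idx, , drop = FALSE]
  N <- resampleN
  ns <- seq_len(N) - 1L
  out <- numeric(0)
  for (d in seq_len(ncol(X))) {
    x <- X[, d]
    co <- vapply(seq_len(k) - 1L, function(kk) {
      if (kk == 0) mean(x)
      else (2 / N) * sum(x * cos(pi * kk * (2 * ns + 1) / (2 * N)))
    }, numeric(1))
    out <- c(out, abs(co))
  }
  out
}

#' Serialize a conceptual space to JSON
#'
#' @param space a [ConceptualSpace-class].
#' @param path optional file.
#' @return JSON string (invisibly if written).
#' @export
spaceToJSON <- function(space, path = NULL) {
  e <- space@env
  js <- jsonlite::toJSON(list(
    dimension = e$dim, symbols = e$symbols,
    seeds = unname(apply(e$seeds, 1, as.numeric, simplify = FALSE)),
    config = list(gap = e$gap, alpha = e$alpha,
                  entropyScaling = e$entropyScaling,
                  weights = e$weights, tol = e$tol)),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

setMethod("show", "ConceptualSpace", function(object) {
  e <- object@env
  cat("ConceptualSpace:", e$dim, "dimensions,", length(e$symbols),
      "seeds; gap =", e$gap, "alpha =", e$alpha, "\n")
})
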