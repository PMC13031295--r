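# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded internals never
#' disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a string key, staying < 2^31.
# Incremental modular hash: every intermediate stays far below 2^53, so the
# arithmetic is exact in doubles.
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483629
  for (code in utf8ToInt(as.character(key)))
    h <- (h * 131 + code) %% 2147483629
  as.integer(h)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Recursive operations over (possibly nested) lists of numeric arrays.
plist_map <- function(p, f) {
  if (is.list(p)) lapply(p, plist_map, f = f) else f(p)
}

plist_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- plist_map2(a[[k]], b[[k]], f)
    out
  } else f(a, b)
}

plist_zeros_like <- function(p) plist_map(p, function(x) array(0, dim = dim(x) %||% length(x)))

plist_add <- function(a, b) plist_map2(a, b, `+`)

plist_scale <- function(p, s) plist_map(p, function(x) x * s)

# Flatten nested parameter list to a single numeric vector (and back).
plist_unlist <- function(p) unlist(p, use.names = FALSE)

plist_relist <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- p
    out[] <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  out <- fill(skeleton)
  stopifnot(pos == length(vec))
  out
}

# Coerce a gradient structure to the exact shapes of a parameter structure
# (vectors stay vectors, matrices keep their dim).
plist_conform <- function(g, p) {
  if (is.list(p)) {
    keys <- names(p) %||% seq_along(p)
    out <- vector("list", length(p))
    names(out) <- names(p)
    keep <- logical(length(p))
    for (q in seq_along(p)) {
      gk <- g[[keys[q]]]
      if (!is.null(gk)) { out[[q]] <- plist_conform(gk, p[[q]]); keep[q] <- TRUE }
    }
    return(out[keep])
  }
  if (is.null(dim(p))) as.numeric(g) else { dim(g) <- dim(p); g }
}

plist_max_abs <- function(p) {
  m <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else m <<- max(m, max(abs(x), 0))
    invisible(NULL)
  }
  walk(p)
  m
}

# Seeded Glorot-style initialization for a fan_in x fan_out weight matrix.
init_weight <- function(fan_in, fan_out, rng_scale = 1) {
  s <- rng_scale * sqrt(2 / (fan_in + fan_out))
  matrix(stats::rnorm(fan_in * fan_out, sd = s), fan_in, fan_out)
}

stop_sc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
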