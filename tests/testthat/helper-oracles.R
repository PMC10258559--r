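# Independent oracles used to validate the package's implementations.
# These deliberately share no code with the package: the mixed-model
# oracle builds the dense marginal covariance explicitly, the geometry
# and matching oracles enumerate, and the image oracles work per pixel.

# ---- dense multivariate-normal likelihood for nested random intercepts ----

# -2 log likelihood with fixed effects profiled out, from the explicit
# n x n covariance  V = sum_l tau2_l Z_l Z_l' + s0 I
oracle_dense_nll2 <- function(tau2, s0, y, X, id_list) {
  n <- length(y)
  V <- diag(s0, n)
  for (l in seq_along(id_list)) {
    Z <- outer(id_list[[l]], id_list[[l]], "==") * 1
    V <- V + tau2[l] * Z
  }
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  A <- crossprod(X, Vi_X)
  b <- crossprod(X, Vi_y)
  beta <- solve(A, b)
  n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y * Vi_y) - sum(b * beta)
}

# dense ML fit by direct optimization over log variances, multi-start
oracle_dense_ml <- function(y, X, id_list, n_starts = 3L) {
  L <- length(id_list)
  vt <- stats::var(y)
  if (vt <= 0) return(list(loglik = Inf))
  obj <- function(par) {
    oracle_dense_nll2(exp(par[seq_len(L)]) * vt, exp(par[L + 1L]) * vt,
                      y, X, id_list)
  }
  starts <- list(rep(log(0.5), L + 1L),
                 c(rep(log(0.05), L), log(0.9)),
                 c(rep(log(1), L), log(0.2)))
  best <- Inf
  for (s in starts[seq_len(n_starts)]) {
    o <- stats::nlminb(s, obj, lower = rep(-30, L + 1L),
                       upper = rep(8, L + 1L))
    if (o$objective < best) best <- o$objective
  }
  list(loglik = -best / 2)
}

# random small nested dataset for oracle-equivalence checks
random_tiny_dataset <- function(seed) {
  set.seed(seed)
  L <- sample(1:3, 1)
  n_units <- sample(2:4, L, replace = TRUE)
  reps <- sample(2:4, 1)
  key <- expand.grid(lapply(n_units, seq_len))
  names(key) <- paste0("lv", seq_len(L))
  key <- key[rep(seq_len(nrow(key)), each = reps), , drop = FALSE]
  n <- nrow(key)
  if (n > 60) key <- key[seq_len(60), , drop = FALSE]
  n <- nrow(key)
  for (l in seq_len(L)) {
    key[[l]] <- do.call(paste, c(key[seq_len(l)], sep = "."))
  }
  with_fixed <- sample(c(TRUE, FALSE), 1)
  if (with_fixed) {
    # condition is an attribute of the innermost units
    u_inner <- unique(key[[L]])
    key$condition <- rep_len(c("a", "b"),
                             length(u_inner))[match(key[[L]], u_inner)]
  }
  tau2 <- stats::runif(L, 0, 2) * sample(c(0, 1), L, replace = TRUE,
                                         prob = c(0.25, 0.75))
  s0 <- stats::runif(1, 0.2, 2)
  y <- stats::rnorm(n, 0, sqrt(s0))
  for (l in seq_len(L)) {
    u <- stats::rnorm(length(unique(key[[l]])), 0, sqrt(tau2[l]))
    y <- y + u[match(key[[l]], unique(key[[l]]))]
  }
  if (with_fixed) y <- y + 1.5 * (key$condition == "b")
  key$y <- y
  list(table = key, levels = paste0("lv", seq_len(L)),
       fixed = if (with_fixed) "condition" else NULL)
}

# ---- brute-force one-to-one matching / assignment -----------------------

# maximum-cardinality bipartite matching within a radius (augmenting paths)
oracle_max_matching <- function(A, B, radius) {
  nA <- nrow(A)
  nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(0L)
  ok <- matrix(FALSE, nA, nB)
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      ok[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2)) <= radius
    }
  }
  match_b <- rep(0L, nB)
  try_kuhn <- function(i, seen) {
    for (j in which(ok[i, ])) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (match_b[j] == 0L || Recall(match_b[j], seen)) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  m <- 0L
  for (i in seq_len(nA)) {
    if (try_kuhn(i, rep(FALSE, nB))) m <- m + 1L
  }
  m
}

# optimal frame-to-frame assignment (min total distance, links <= max_link,
# maximal number of links) by enumeration over injections; <= 4 points
oracle_assignment <- function(open, new, max_link) {
  no <- nrow(open)
  nn <- nrow(new)
  big <- 1e6
  best <- NULL
  best_cost <- Inf
  idx_new <- seq_len(nn)
  subsets <- function(v, k) if (k == 0) list(integer(0)) else utils::combn(v, k, simplify = FALSE)
  for (k in seq(min(no, nn), 0)) {
    for (oi in subsets(seq_len(no), k)) {
      for (nj in subsets(idx_new, k)) {
        perms <- if (k == 0) list(integer(0)) else all_perms(nj)
        for (p in perms) {
          d <- if (k) mapply(function(i, j) {
            sqrt(sum((open[i, c("x", "y")] - new[j, c("x", "y")])^2))
          }, oi, p) else numeric(0)
          if (all(d <= max_link)) {
            cost <- (no + nn - 2 * k) * big + sum(d)
            if (cost < best_cost) {
              best_cost <- cost
              best <- if (k) cbind(open = oi, new = p) else
                cbind(open = integer(0), new = integer(0))
            }
          }
        }
      }
    }
    if (!is.null(best)) break   # maximal k found
  }
  best
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# ---- per-pixel set-operation oracle for mask differencing ---------------

oracle_dynamic_regions <- function(prev, curr, nxt, lab, pixel_size) {
  cm <- curr == lab
  pm <- if (is.null(prev)) NULL else prev == lab
  nm <- if (is.null(nxt)) NULL else nxt == lab
  list(
    protrusion = if (is.null(pm)) NA_real_ else sum(cm & !pm) * pixel_size^2,
    retraction = if (is.null(nm)) NA_real_ else sum(cm & !nm) * pixel_size^2,
    shortlived = if (is.null(pm) || is.null(nm)) NA_real_ else
      sum(cm & !pm & !nm) * pixel_size^2
  )
}

# ---- misc scalar oracles ------------------------------------------------

# type-7 quantile (linear interpolation between order statistics)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

oracle_moving_average <- function(v, window) {
  n <- length(v)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(v[(i - h):(i + h)])
  }
  out
}
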