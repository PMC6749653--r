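# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never
#' perturb the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# derive a child seed from a base seed and a salt, kept within 32-bit range
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt_num <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 48271 + salt_num) %% 2147483629) + 1L
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# stratified fold assignment reused by GA, router, and all regressors so
# that cross-validated comparisons between branches are paired
make_folds <- function(n, k = 5L, seed = 1L, strata = NULL) {
  stopifnot(n >= k)
  local_seed(seed, {
    if (is.null(strata)) strata <- rep(1L, n)
    strata <- as.integer(factor(strata))
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

is_binary_matrix_col <- function(x) all(x %in% c(0, 1))
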