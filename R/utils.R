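`%||%` <- function(x, y) if (is.null(x)) y else x

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# enumerate permutations of 1..k (k is tiny: number of latent classes)
perms_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

abort_input <- function(msg) stop(msg, call. = FALSE)

# seed the RNG for the calling function's scope and restore the previous
# global state on its exit, so seeded fits/simulations leave callers' RNG
# streams untouched
local_seed_restore <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
}
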