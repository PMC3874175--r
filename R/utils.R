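# Internal helpers shared across modules.

#' @importFrom stats rnorm rlnorm rexp rpois runif sd median wilcox.test
#'   fisher.test cor.test phyper p.adjust integrate dexp pexp dgamma pgamma
#'   ecdf setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit child seed for a named random stream, so that the
# draws of one sub-generator do not perturb the others.
child_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, orthologs = 211L, motifs = 307L, peaks = 401L,
               pdi = 503L, coexpression = 601L, pipeline = 701L,
               lengths = 809L, misc = 907L)
  if (!stream %in% names(offsets)) {
    off <- sum(utf8ToInt(stream)) %% 1000L + 11L
  } else {
    off <- offsets[[stream]]
  }
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + off * 1000003
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Standard error of the mean; 0 (with an n=1 flag upstream) for single values.
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n <= 1L) return(0)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
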