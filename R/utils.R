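#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps every exported function reproducible
# without clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-stage seed from one master seed so stages are reproducible
# standalone. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stages <- c(
    simulate = 11L, featurize = 23L, select = 37L, balance = 53L,
    train = 71L, score = 89L, evaluate = 107L, split = 131L
  )
  off <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# z-score columns; constant columns are centred but left unscaled.
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  scaled <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(scaled, "center") <- center
  attr(scaled, "scale") <- scale
  scaled
}

dep_log <- function(..., level = "INFO") {
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
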