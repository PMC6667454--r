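# Internal numeric helpers shared across modules.

# Log-sum-exp with max subtraction; handles all -Inf inputs by returning -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Floor used wherever hard zeros must survive the log domain (zero context
# priors, rounded-to-zero LDA posteriors).
LOG_FLOOR <- -1e10

log_floor <- function(x, floor = LOG_FLOOR) {
  x[!is.finite(x) & x < 0] <- floor
  pmax(x, floor)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package randomness never perturbs
# the user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Levenshtein distance between two label sequences (character vectors),
# counting insertions, deletions and substitutions at the element level.
levenshtein <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cost <- if (a[[i]] == b[[j]]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# First index of the maximum (documented tie-break: lowest index).
argmax_first <- function(x) which.max(x)
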