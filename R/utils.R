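# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers never disturb user code.
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

# Row means / sample (n-1) standard deviations without apply() overhead.
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

is_bipolar <- function(p) all(p == 1 | p == -1)

pattern_key <- function(p) paste(ifelse(p > 0, "+", "-"), collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a
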