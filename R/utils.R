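# Internal helpers: argument checking, seeded RNG scoping, TSV conventions.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stopf("'%s' = %g is out of range", name, x)
  }
  as.numeric(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so seeded simulators do not perturb the session.
with_seed <- function(seed, expr) {
  seed <- assert_count(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of one global seed into per-stage streams.
# Keeps derived seeds in [1, 2^31 - 2] (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  seed <- assert_count(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483646) + 1L
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#", ...)
}

write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

provenance_comment <- function(params = list()) {
  ps <- if (length(params)) {
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  sprintf("rbpengage %s %s", as.character(utils::packageVersion("rbpengage")), ps)
}
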