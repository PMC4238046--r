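# Internal helpers shared across modules.

# Population (divide-by-n) standard deviation. The Z-score transformation and
# the Z-ratio denominator both use the population convention so that a
# transformed column has SD exactly 1.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Strict scalar checks used by configuration validators.
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf,
                          open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok) {
    stop(sprintf("'%s' must be a single number in %s%g, %g%s", name,
                 if (open_min) "(" else "[", min, max,
                 if (open_max) ")" else "]"), call. = FALSE)
  }
  as.numeric(x)
}

# TSV dialect used for every table the package exchanges: tab-separated,
# UTF-8, '#' comment lines, no quoting, no row names.
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
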