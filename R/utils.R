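#' @keywords internal
"_PACKAGE"

# Percentage rounded to 1 decimal, the reporting convention used by every
# summary table in the package. Returns 0 (not NaN) for a 0 denominator.
pct1 <- function(num, den) {
  if (length(den) == 1L && (is.na(den) || den == 0)) return(0)
  round(100 * num / den, 1)
}

round1 <- function(x) round(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

# Stable order by a character id (C locale via explicit method) so that every
# "ties broken by locus id" contract is reproducible across platforms.
id_order <- function(ids) order(ids, method = "radix")
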