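`%||%` <- function(a, b) if (is.null(a)) b else a

## 3'-terminal base of an interval in transcription direction (0-based)
terminal_pos <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

## transcription-direction 5'-most base
head_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

## offset of genomic position `pos` from anchor in transcription direction
tx_offset <- function(pos, anchor, strand) {
  ifelse(strand == "+", pos - anchor, anchor - pos)
}

interval_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = ":")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## population standard deviation (denominator n), the convention used by the
## feature-local peak threshold
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## deterministic seed derivation for named substreams; keeps results < 2^31
derive_seed <- function(seed, stage) {
  stage_off <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(seed) * 1009L + stage_off) %% .Machine$integer.max
}

csv_int <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)
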