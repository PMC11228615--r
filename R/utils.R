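# Shared low-level helpers.

# the 20 standard amino-acid letters
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.is_gap <- function(x) x == "-" | x == "." | is.na(x)

.check_aa <- function(seq, id = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad) > 0L)
    stop(sprintf("%s contains non-amino-acid letters: %s", id,
                 paste(bad, collapse = ",")), call. = FALSE)
  if (length(chars) == 0L) stop(sprintf("%s is empty", id), call. = FALSE)
  invisible(TRUE)
}

# Match an observed residue string against a motif pattern.
# 'X' in the pattern matches any non-gap residue; gaps never match.
# Pattern "absent" is handled by the caller (anchor-specific semantics).
.pattern_match <- function(observed, pattern) {
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  obs <- strsplit(observed, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  if (any(.is_gap(obs))) return(FALSE)
  all(pat == "X" | obs == pat)
}

# uniform draw of a residue different from 'from'
.mutate_residue <- function(from, rng_pool = AA20) {
  pool <- setdiff(rng_pool, from)
  pool[sample.int(length(pool), 1L)]
}

.seed_guard <- function(seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    return(invisible(old))
  }
  invisible(NULL)
}
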