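#' @import Biostrings
#' @importFrom stats rbinom runif setNames median sd cor complete.cases aggregate
#' @importFrom utils write.table read.table
NULL

# Classed conditions: every user-facing failure mode gets its own class so
# callers can distinguish them programmatically.
am_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "ampliMeth_error")))
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
rev_comp <- function(x) {
  out <- character(length(x))
  nonempty <- nchar(x) > 0L
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nonempty]))
    )
  }
  out
}

# Three-letter space conversions used for both reference and reads.
ct_convert <- function(x) chartr("C", "T", x)
ga_convert <- function(x) chartr("G", "A", x)

# phred+33 <-> integer scores
phred_to_int <- function(q) {
  if (nchar(q) == 0L) return(integer(0))
  utf8ToInt(q) - 33L
}
int_to_phred <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(pmin(93L, pmax(0L, as.integer(v))) + 33L)
}

# Seeds derived from a master seed stay within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# Evaluate `expr` under seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
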