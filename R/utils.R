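# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Reverse-complement nucleotide strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors (alphabet A/C/G/T/N).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# "chr1" and "1" refer to the same contig in mixed-source interval work
strip_chr <- function(x) sub("^chr", "", x)

# stable numeric formatting for emitted tables (no scientific notation)
fmt_num <- function(x, digits = NA) {
  out <- ifelse(is.na(x), "NA",
                if (is.na(digits)) format(x, scientific = FALSE, trim = TRUE)
                else formatC(x, format = "f", digits = digits))
  out
}

# collapse a numeric vector into an rMATS-style comma list ("12,7,10"); NA -> "NA"
commas <- function(v, digits = NA) {
  vapply(v, function(vv) {
    paste(fmt_num(vv, digits = digits), collapse = ",")
  }, "", USE.NAMES = FALSE)
}

# split an rMATS comma list into numeric, mapping "NA"/"" to NA;
# any other non-numeric token is a parse error (dialect drift fails loudly)
split_commas <- function(s, what = "value", line = NA) {
  toks <- strsplit(as.character(s), ",", fixed = TRUE)
  lapply(seq_along(toks), function(i) {
    tk <- trimws(toks[[i]])
    tk[tk == ""] <- "NA"
    bad <- tk != "NA" & is.na(suppressWarnings(as.numeric(tk)))
    if (any(bad)) {
      stop_fmt("cannot parse %s '%s'%s", what, tk[bad][1],
               if (is.na(line[i] %||% NA)) "" else sprintf(" (line %d)", line[i]))
    }
    suppressWarnings(as.numeric(ifelse(tk == "NA", NA, tk)))
  })
}
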