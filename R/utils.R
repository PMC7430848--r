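#' Reverse complement of a DNA string
#'
#' Works on plain character strings over {A,C,G,T,N}; N maps to N.
#'
#' @param x character scalar.
#' @return character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# internal: run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# internal: validate a DNA string over the A/C/G/T/N alphabet
check_alphabet <- function(bases, what = "sequence") {
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
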