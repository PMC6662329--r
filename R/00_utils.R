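#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
SEX_LEVELS <- c("male", "female", "unknown")
AGE_LEVELS <- c("calf", "juvenile", "adult", "unknown")

# standard genetic code keyed by codon string; "*" marks stops
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

translate_codon <- function(codon) {
  aa <- .codon_table[codon]
  if (anyNA(aa)) {
    stop("ambiguous or invalid codon: ", paste(codon[is.na(aa)], collapse = ", "),
         call. = FALSE)
  }
  unname(aa)
}

is_stop_codon <- function(codon) {
  unname(.codon_table[codon] == "*")
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds through this
#' function so that a single master seed makes a multi-stage run
#' bit-reproducible while keeping the stages' streams distinct. The result
#' always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param stream integer stream index (stage number, replicate id, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream = 1L) {
  master <- as.numeric(master)
  stream <- as.numeric(stream)
  as.integer((abs(master) * 48271 + stream * 16807 + 1) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
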