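# Internal helpers shared across modules.

#' @importFrom stats optimize optim qgamma rgamma runif rexp acf setNames
#'   rbinom sd quantile pchisq chisq.test
#' @importFrom utils read.delim write.table head tail
NULL

# IUPAC nucleotide code -> base set. Gap is handled separately.
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.valid_seq_chars <- c(names(.iupac), "-")

# Evaluate fn() with a temporarily seeded RNG, restoring prior state.
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  fn()
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# split a sequence string into a character vector
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

degap <- function(s) gsub("-", "", s, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
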