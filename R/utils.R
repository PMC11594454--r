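`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not perturb user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Format numbers for report/BED output: plain decimal notation, no padding,
# stable across locales so identical inputs give byte-identical files.
.fmtNum <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         sprintf("%.0f", x),
         sub("0+$", "", sprintf("%.6f", x)))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# seqlengths from a DNAStringSet or a named numeric vector
.seqLens <- function(assembly) {
  if (is(assembly, "DNAStringSet")) {
    stats::setNames(BiocGenerics::width(assembly), names(assembly))
  } else if (is.numeric(assembly) && !is.null(names(assembly))) {
    assembly
  } else .stopf("expected a DNAStringSet or a named numeric vector of lengths")
}
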