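# Internal helpers shared across modules.

# Boltzmann factor kT at 37 C in kcal/mol; single source for engine and oracle.
.kT37 <- 0.0019872041 * 310.15

#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef predict BIC glm binomial plogis var rnorm runif
#' @importFrom utils read.delim write.table head tail
NULL

.assertDNA <- function(x, what = "sequence", allowN = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x))
    stop(what, " contains characters outside {A,C,G,T",
         if (allowN) ",N", "}: ", x, call. = FALSE)
  invisible(x)
}

# DNA or RNA input, uppercased, T -> U
.toRNA <- function(x) chartr("Tt", "Uu", toupper(x))

# encode RNA string as integers 0=A 1=C 2=G 3=U for the folding engine
.encodeRNA <- function(x, what = "sequence") {
  x <- .toRNA(x)
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes))
    stop(what, " contains characters without thermodynamic parameters ",
         "(only A/C/G/U(T) allowed): ", x, call. = FALSE)
  codes
}

.revcompDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring with 0-based half-open coordinates
.slice0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

# flat key = value config files (numbers parsed, everything else kept as text)
.readKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed key = value line in ", path, call. = FALSE)
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- trimws(vapply(parts, `[`, "", 2L))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

.writeKeyValue <- function(x, path, header = NULL) {
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, "")
  lines <- paste(names(x), "=", vals)
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "skipAO", mustWork = FALSE)
  if (!nzchar(path))
    stop("bundled data file not found: ", file, call. = FALSE)
  path
}

# run a block with a temporary RNG state seeded from `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
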