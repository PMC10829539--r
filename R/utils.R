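# Shared internals: seeded RNG scoping, alphabets, codon table, small helpers.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

# Most frequent human codon per amino acid; deterministic back-translation.
HUMAN_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
  G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
  M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
  S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC",
  `*` = "TGA"
)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Single character string -> character vector of residues/bases.
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

c2s <- function(x) paste(x, collapse = "")

# Coerce sequence-ish input (character, XString, XStringSet) to character.
as_seq_character <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("cannot interpret object of class '", class(x)[1], "' as sequence(s)")
  }
  out
}
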