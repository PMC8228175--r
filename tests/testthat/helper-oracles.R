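# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the scoring oracle works on characters with an
# explicit pairing table, and the circuit oracles are direct formula
# transcriptions.

# positionwise match count by explicit base/pair lookup (no bit tricks)
brute_force_match <- function(a, b, mode = "complement") {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  m <- min(length(ca), length(cb))
  wc <- c(A = "T", T = "A", C = "G", G = "C")
  hits <- vapply(seq_len(m), function(i) {
    if (mode == "identity") ca[i] == cb[i] else unname(wc[ca[i]]) == cb[i]
  }, logical(1))
  list(count = sum(hits), min_length = m, score = 100 * sum(hits) / m)
}

# random DNA string
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# default-constant shorthand used by frozen expected values
pc <- physical_constants()
sil <- material_params("silicene")
gra <- material_params("graphene")
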