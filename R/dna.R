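#' Validated nucleotide sequence
#'
#' A single-stranded DNA sequence over the alphabet {A, C, G, T}.  Input is
#' uppercased; any other symbol is rejected with the offending position
#' named.
#'
#' @param bases a single character string of bases (or a
#'   [Biostrings::DNAString]).
#' @param id identifier label.
#' @return Object of class `nucleotide_sequence`.
#' @examples
#' nucleotide_sequence("gtac", id = "probe1")
#' @export
nucleotide_sequence <- function(bases, id = "seq") {
  bases <- toupper(as.character(bases))
  if (length(bases) != 1 || is.na(bases) || nchar(bases) == 0) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop(sprintf("invalid symbol '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], id))
  }
  structure(list(id = as.character(id), bases = bases),
            class = "nucleotide_sequence")
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  b <- x$bases
  if (nchar(b) > 60) b <- paste0(substr(b, 1, 57), "...")
  cat(sprintf("<%s> %d nt: %s\n", x$id, nchar(x$bases), b))
  invisible(x)
}

# 2-bit base code: A=00, C=01, G=10, T=11.  Watson-Crick complementarity is
# exactly bitwise XOR == 11 under this code.
BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

as_nucleotide <- function(x, id = "seq") {
  if (inherits(x, "nucleotide_sequence")) x else nucleotide_sequence(x, id)
}

base_codes <- function(seq) {
  unname(BASE_CODE[strsplit(seq$bases, "", fixed = TRUE)[[1]]])
}

#' Two-bit binary encoding of a DNA sequence
#'
#' Encodes each base as two bits (A -> 00, C -> 01, G -> 10, T -> 11),
#' giving a bit string of length 2 x sequence length.  The code is chosen so
#' that Watson-Crick complementary bases differ in both bits: complement
#' testing reduces to bitwise XOR equal to 11.
#'
#' @param seq a [nucleotide_sequence] (or a plain base string).
#' @return A single character string of 0/1 digits.
#' @examples
#' encode_binary("GTAC") # "10110001"
#' @export
encode_binary <- function(seq) {
  seq <- as_nucleotide(seq)
  codes <- base_codes(seq)
  paste0(ifelse(bitwAnd(codes, 2L) > 0L, "1", "0"),
         ifelse(bitwAnd(codes, 1L) > 0L, "1", "0"),
         collapse = "")
}

#' Decode a two-bit binary string back to bases
#'
#' Inverse of [encode_binary].
#'
#' @param bits character string of 0/1 digits, even length.
#' @param id identifier for the decoded sequence.
#' @return A [nucleotide_sequence].
#' @export
decode_binary <- function(bits, id = "decoded") {
  bits <- as.character(bits)
  if (nchar(bits) %% 2 != 0 || grepl("[^01]", bits)) {
    stop("bit string must contain only 0/1 and have even length")
  }
  d <- strsplit(bits, "", fixed = TRUE)[[1]]
  hi <- as.integer(d[seq(1, length(d), by = 2)])
  lo <- as.integer(d[seq(2, length(d), by = 2)])
  nucleotide_sequence(paste(names(BASE_CODE)[2L * hi + lo + 1L],
                            collapse = ""), id)
}

#' Reverse complement of a sequence
#' @param seq a [nucleotide_sequence] (or plain base string).
#' @return A [nucleotide_sequence].
#' @export
reverse_complement <- function(seq) {
  seq <- as_nucleotide(seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq$bases)))
  nucleotide_sequence(rc, paste0(seq$id, "_rc"))
}

#' Positionwise match score of two sequences
#'
#' Compares the two sequences position by position over their minimum
#' length and reports the match count and Match-Score (the percentage of
#' matching positions).  In `"identity"` mode a position matches when the
#' bases are equal (XOR of the 2-bit codes is 00); in `"complement"` mode
#' (the hybridization-relevant one) it matches when the bases are
#' Watson-Crick pairs A-T or C-G (XOR of the 2-bit codes is 11).
#'
#' @param a,b [nucleotide_sequence] objects (or plain base strings).
#' @param mode `"complement"` (default) or `"identity"`.
#' @param reverse_target reverse `b` before comparison, for antiparallel
#'   hybridization; default `FALSE` (plain positionwise comparison).
#' @return Object of class `hybridization_result`: list with `match_count`,
#'   `min_length`, `match_score` (percent), `mode`, `probe_id`, `target_id`.
#' @examples
#' match_score("ACGT", "TGCA", mode = "complement")$match_score # 100
#' @export
match_score <- function(a, b, mode = c("complement", "identity"),
                        reverse_target = FALSE) {
  mode <- match.arg(mode)
  a <- as_nucleotide(a, "probe")
  b <- as_nucleotide(b, "target")
  ca <- base_codes(a)
  cb <- base_codes(b)
  if (reverse_target) cb <- rev(cb)
  m <- min(length(ca), length(cb))
  x <- bitwXor(ca[seq_len(m)], cb[seq_len(m)])
  count <- if (mode == "identity") sum(x == 0L) else sum(x == 3L)
  structure(
    list(match_count = count, min_length = m,
         match_score = 100 * count / m, mode = mode,
         probe_id = a$id, target_id = b$id),
    class = "hybridization_result"
  )
}

#' @export
print.hybridization_result <- function(x, ...) {
  cat(sprintf("Hybridization (%s mode): %d/%d positions, Match-Score %.2f%%\n",
              x$mode, x$match_count, x$min_length, x$match_score))
  invisible(x)
}

#' Ion-release model linking hybridization to solution chemistry
#'
#' Each matched base pair formed during hybridization/extension releases a
#' fixed number of protons into the reaction volume; the resulting
#' concentration change shifts the channel's external surface carrier
#' density through a linear charge-to-density gain.  The defaults (one
#' proton per matched base, 1 uL volume, 1e-7 mol/L neutral baseline, gain
#' 1e19 (m^-2)/(mol/L)) are illustrative model settings, not measured
#' quantities.
#'
#' @param ions_per_match protons released per matched base (count).
#' @param solution_volume reaction volume (L).
#' @param baseline_h baseline proton concentration (mol/L).
#' @param charge_to_density_gain carrier-density shift per unit proton
#'   concentration change ((per m^2) / (mol/L)).
#' @return Object of class `ion_release_model`.
#' @export
ion_release_model <- function(ions_per_match = 1,
                              solution_volume = 1e-6,
                              baseline_h = 1e-7,
                              charge_to_density_gain = 1e19) {
  vals <- c(ions_per_match = ions_per_match,
            solution_volume = solution_volume,
            baseline_h = baseline_h,
            charge_to_density_gain = charge_to_density_gain)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ion-release model parameters must be positive")
  }
  structure(as.list(vals), class = "ion_release_model")
}

#' Proton concentration change from a hybridization event
#'
#' delta [H+] = ions_per_match x match_count / (N_A x volume): the molar
#' concentration of protons released by the matched bases into the reaction
#' volume.  Linear in the match count.
#'
#' @param result a [hybridization_result] (or a bare match count).
#' @param model an [ion_release_model].
#' @param constants a [physical_constants] object (supplies Avogadro's
#'   number).
#' @return Concentration change (mol/L), >= 0.
#' @export
hplus_from_hybridization <- function(result, model = ion_release_model(),
                                     constants = physical_constants()) {
  stopifnot(inherits(model, "ion_release_model"))
  count <- if (inherits(result, "hybridization_result")) {
    result$match_count
  } else {
    as.numeric(result)
  }
  if (any(count < 0)) stop("match count must be non-negative")
  model$ions_per_match * count / (constants$avogadro * model$solution_volume)
}

#' pH of a proton concentration
#'
#' pH = -log10([H+]), the standard chemical definition.
#'
#' @param h_concentration proton concentration (mol/L), > 0; vectorized.
#' @return pH value.
#' @examples
#' ph_from_h(1e-7) # 7
#' @export
ph_from_h <- function(h_concentration) {
  if (any(!is.finite(h_concentration)) || any(h_concentration <= 0)) {
    stop("proton concentration must be strictly positive")
  }
  -log10(h_concentration)
}

#' Carrier-density shift from a proton concentration change
#'
#' delta n* = gain x delta [H+]; the external surface-charge component that
#' feeds the channel carrier state.
#'
#' @param delta_h proton concentration change (mol/L); vectorized.
#' @param model an [ion_release_model].
#' @return Sheet-density shift (per m^2).
#' @export
hybridization_to_carrier_shift <- function(delta_h,
                                           model = ion_release_model()) {
  stopifnot(inherits(model, "ion_release_model"))
  model$charge_to_density_gain * delta_h
}

#' End-to-end frequency shift from a probe/target pair
#'
#' Composes the full transduction chain: match score -> proton release ->
#' pH change -> carrier-density shift -> quantum capacitance -> LC resonant
#' frequency.  The baseline operating point sits at the material's residual
#' carrier density; hybridization adds carriers, raising C_Q and lowering
#' the resonant frequency, so the reported shift f(baseline) - f(hybridized)
#' is non-negative and grows with the match score.
#'
#' @param probe,target [nucleotide_sequence] objects (or base strings).
#' @param model an [ion_release_model].
#' @param material a [material_params] object.
#' @param geometry a [device_geometry] object.
#' @param readout an [lc_readout] object.
#' @param mode match mode, `"complement"` (default) or `"identity"`.
#' @param reverse_target reverse the target before comparison.
#' @param baseline_n_per_cm2 baseline carrier concentration (per cm^2);
#'   defaults to the material's residual density.
#' @param constants a [physical_constants] object.
#' @return List of class `detection_result` with the stage outputs:
#'   `score` (a [hybridization_result]), `delta_h_mol_per_l`, `ph`,
#'   `delta_n_per_m2`, `cq_baseline_f`, `cq_hybridized_f`,
#'   `freq_baseline_hz`, `freq_hybridized_hz`, `freq_shift_hz`.
#' @export
detect_end_to_end <- function(probe, target,
                              model = ion_release_model(),
                              material = material_params("silicene"),
                              geometry = device_geometry_for(material),
                              readout = lc_readout(),
                              mode = c("complement", "identity"),
                              reverse_target = FALSE,
                              baseline_n_per_cm2 =
                                material$residual_carrier_density,
                              constants = physical_constants()) {
  mode <- match.arg(mode)
  score <- match_score(probe, target, mode = mode,
                       reverse_target = reverse_target)
  delta_h <- hplus_from_hybridization(score, model, constants)
  ph <- ph_from_h(model$baseline_h + delta_h)
  delta_n <- hybridization_to_carrier_shift(delta_h, model)
  n0 <- max(baseline_n_per_cm2 * PER_CM2_TO_PER_M2,
            material$residual_carrier_density * PER_CM2_TO_PER_M2)
  cq0 <- cq_degenerate(n0, material, geometry, constants)
  cq1 <- cq_degenerate(n0 + delta_n, material, geometry, constants)
  f0 <- resonant_frequency(readout, cq0)
  f1 <- resonant_frequency(readout, cq1)
  structure(
    list(score = score, delta_h_mol_per_l = delta_h, ph = ph,
         delta_n_per_m2 = delta_n,
         cq_baseline_f = cq0, cq_hybridized_f = cq1,
         freq_baseline_hz = f0, freq_hybridized_hz = f1,
         freq_shift_hz = f0 - f1),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "DNA detection: score %.1f%% -> dH+ %.3g mol/L (pH %.3f) -> dn %.3g m^-2 -> df %.4g Hz\n",
    x$score$match_score, x$delta_h_mol_per_l, x$ph, x$delta_n_per_m2,
    x$freq_shift_hz))
  invisible(x)
}
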