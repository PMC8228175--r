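#' Seeded synthetic probe/target pairs with planted match scores
#'
#' Generates `n_pairs` probe sequences uniformly at random and, for each,
#' a target that is the positionwise Watson-Crick complement except at a
#' planted set of `round(mismatch_frac * length)` positions, where the
#' complementary base is replaced by a random non-complementary one.  The
#' complement-mode match score of every pair is therefore exactly
#' 100 * (1 - round(mismatch_frac * length) / length) percent by
#' construction, which makes these pairs ground-truth fixtures for the
#' scoring algorithm.
#'
#' @param n_pairs number of probe/target pairs.
#' @param length sequence length (bases).
#' @param mismatch_frac planted mismatch fraction in `[0, 1]`.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return A `data.frame` with columns `probe_id`, `target_id`, `probe`,
#'   `target`, `planted_mismatches`, `expected_score_pct`.
#' @examples
#' fx <- make_fixture_pairs(3, length = 20, mismatch_frac = 0.25, seed = 1)
#' fx$expected_score_pct
#' @export
make_fixture_pairs <- function(n_pairs, length, mismatch_frac = 0,
                               seed = 1L) {
  if (n_pairs < 1 || length < 1) stop("n_pairs and length must be >= 1")
  if (mismatch_frac < 0 || mismatch_frac > 1) {
    stop("mismatch_frac must lie in [0, 1]")
  }
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  k <- round(mismatch_frac * length)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_pairs), function(i) {
    p <- sample(bases, length, replace = TRUE)
    t <- unname(comp[p])
    if (k > 0) {
      pos <- sample.int(length, k)
      for (j in pos) {
        # any base other than the complement breaks the Watson-Crick pair
        t[j] <- sample(setdiff(bases, comp[p[j]]), 1)
      }
    }
    data.frame(probe_id = sprintf("probe_%04d", i),
               target_id = sprintf("target_%04d", i),
               probe = paste(p, collapse = ""),
               target = paste(t, collapse = ""),
               planted_mismatches = k,
               expected_score_pct = 100 * (length - k) / length)
  })
  do.call(rbind, rows)
}

#' Write fixture pairs as FASTA files with a ground-truth sidecar
#'
#' @param pairs output of [make_fixture_pairs].
#' @param probe_path,target_path FASTA output paths.
#' @param truth_path CSV sidecar with the planted scores; `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_fixture_fasta <- function(pairs, probe_path, target_path,
                                truth_path = NULL) {
  probes <- Biostrings::DNAStringSet(pairs$probe)
  names(probes) <- pairs$probe_id
  targets <- Biostrings::DNAStringSet(pairs$target)
  names(targets) <- pairs$target_id
  Biostrings::writeXStringSet(probes, probe_path)
  Biostrings::writeXStringSet(targets, target_path)
  paths <- c(probe_path, target_path)
  if (!is.null(truth_path)) {
    utils::write.csv(
      pairs[, c("probe_id", "target_id", "planted_mismatches",
                "expected_score_pct")],
      truth_path, row.names = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Read probe/target FASTA files as paired sequences
#'
#' Records are paired by order; both files must contain the same number of
#' records.
#'
#' @param probe_path,target_path FASTA files.
#' @return A list of lists, each with `probe` and `target`
#'   [nucleotide_sequence] objects.
#' @export
read_sequence_pairs <- function(probe_path, target_path) {
  probes <- Biostrings::readDNAStringSet(probe_path)
  targets <- Biostrings::readDNAStringSet(target_path)
  if (length(probes) != length(targets)) {
    stop("probe and target FASTA files must contain the same number of records")
  }
  lapply(seq_along(probes), function(i) {
    list(probe = nucleotide_sequence(as.character(probes[[i]]),
                                     names(probes)[i]),
         target = nucleotide_sequence(as.character(targets[[i]]),
                                      names(targets)[i]))
  })
}

#' Score a set of probe/target pairs through the full detection chain
#'
#' Runs [detect_end_to_end] on every pair and tabulates the stage outputs.
#'
#' @param pairs list of pairs from [read_sequence_pairs], or a fixture
#'   `data.frame` from [make_fixture_pairs].
#' @inheritParams detect_end_to_end
#' @return A `data.frame` with columns `probe_id`, `target_id`,
#'   `match_count`, `min_length`, `match_score_pct`, `delta_h_mol_per_l`,
#'   `ph`, `delta_n_per_m2`, `freq_shift_hz`.
#' @export
hybridize_pairs <- function(pairs,
                            model = ion_release_model(),
                            material = material_params("silicene"),
                            geometry = device_geometry_for(material),
                            readout = lc_readout(),
                            mode = c("complement", "identity"),
                            reverse_target = FALSE,
                            constants = physical_constants()) {
  mode <- match.arg(mode)
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      list(probe = nucleotide_sequence(pairs$probe[i], pairs$probe_id[i]),
           target = nucleotide_sequence(pairs$target[i], pairs$target_id[i]))
    })
  }
  rows <- lapply(pairs, function(p) {
    r <- detect_end_to_end(p$probe, p$target, model, material, geometry,
                           readout, mode = mode,
                           reverse_target = reverse_target,
                           constants = constants)
    data.frame(probe_id = r$score$probe_id, target_id = r$score$target_id,
               match_count = r$score$match_count,
               min_length = r$score$min_length,
               match_score_pct = r$score$match_score,
               delta_h_mol_per_l = r$delta_h_mol_per_l, ph = r$ph,
               delta_n_per_m2 = r$delta_n_per_m2,
               freq_shift_hz = r$freq_shift_hz)
  })
  do.call(rbind, rows)
}
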