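# Direct feature_table construction from detection/intensity tensors,
# bypassing alignment, for filter-rule tests.

table_from_tensor <- function(intens, det, sample_types) {
  n_feat <- dim(intens)[1]; n_samp <- dim(intens)[2]; n_rep <- dim(intens)[3]
  samples <- sprintf("S%02d", seq_len(n_samp))
  cols <- expand.grid(rep = seq_len(n_rep), samp = seq_len(n_samp))
  intensity <- matrix(0, n_feat, nrow(cols))
  detection <- matrix(FALSE, n_feat, nrow(cols))
  for (k in seq_len(nrow(cols))) {
    intensity[, k] <- intens[, cols$samp[k], cols$rep[k]]
    detection[, k] <- det[, cols$samp[k], cols$rep[k]]
  }
  holometab:::new_feature_table(
    tibble::tibble(row_id = seq_len(n_feat),
                   mz = 200 + seq_len(n_feat), rt = seq_len(n_feat) / 10,
                   n_members = 1L,
                   spectrum = replicate(n_feat, NULL, simplify = FALSE),
                   metabolite_id = NA_character_),
    intensity, detection,
    tibble::tibble(sample_id = samples[cols$samp], replicate = cols$rep),
    tibble::tibble(sample_id = samples, sample_type = sample_types,
                   organism = samples, taxon_id = NA_character_)
  )
}

random_tensor_table <- function(n_feat = 20, n_bio = 6, n_blank = 2,
                                n_rep = 3, p_detect = 0.5) {
  n_samp <- n_bio + n_blank
  det <- array(runif(n_feat * n_samp * n_rep) < p_detect,
               dim = c(n_feat, n_samp, n_rep))
  intens <- array(runif(n_feat * n_samp * n_rep, 1, 100),
                  dim = dim(det)) * det
  types <- c(rep("fungal", n_bio), rep("blank", n_blank))
  list(table = table_from_tensor(intens, det, types), det = det,
       intens = intens, types = types)
}
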