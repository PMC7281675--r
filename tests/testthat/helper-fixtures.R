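# Small in-code fixtures shared across test files.

# integer-valued random stack wrapped as an irm_sequence
rand_stack <- function(h = 6, w = 6, t = 4, levels = 256, interval = 5,
                       seed = NULL) {
  draw <- function() array(sample(0:(levels - 1), h * w * t, replace = TRUE),
                           dim = c(h, w, t))
  frames <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  irm_sequence(frames, frame_interval = interval)
}

# one-row annotation table in the load_annotations() dialect
annotation_row <- function(platelet_id = "p1",
                           row_min = 1, col_min = 1, row_max = 4, col_max = 4,
                           frame_first = 1, frame_last = 50,
                           onset = 1, filopodia_onset = 4,
                           lamellipodia_onset = 11, spread = 20,
                           endpoint_class = "fully_spread",
                           bg_row_min = 6, bg_col_min = 6,
                           bg_row_max = 8, bg_col_max = 8,
                           index_base = 1) {
  data.frame(platelet_id = platelet_id, row_min = row_min, col_min = col_min,
             row_max = row_max, col_max = col_max, frame_first = frame_first,
             frame_last = frame_last, onset = onset,
             filopodia_onset = filopodia_onset,
             lamellipodia_onset = lamellipodia_onset, spread = spread,
             endpoint_class = endpoint_class, bg_row_min = bg_row_min,
             bg_col_min = bg_col_min, bg_row_max = bg_row_max,
             bg_col_max = bg_col_max, index_base = index_base,
             stringsAsFactors = FALSE)
}

write_annotation_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}
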