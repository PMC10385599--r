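# Shared fixtures: all phantom data are generated in code at test time.

# Desk-scale phantom spec used across tests (64 px; rib period and nodule
# diameter scale with the image side).
desk_spec <- function(...) phantom_spec(image_size = 64L, ...)

# (image, gold mask) pairs for segmenter training.
make_seg_pairs <- function(spec, n, counter_offset = 0L) {
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2L == 0L) "nodule" else "non-nodule"
    s <- generate_sample(spec, lab, counter = counter_offset + i)
    list(image = s$image, mask = s$true_mask)
  })
}

# A dataset written to a throwaway directory; returns the manifest.
make_dataset <- function(spec, n_nodule, n_normal) {
  dir <- tempfile("phantom")
  generate_dataset(spec, n_nodule, n_normal, dir)
}

# Hand-built logistic scorer recognised by predict_prob()/inference_matrix();
# used where tests need fold models with known behaviour.
fake_model <- function(weights, bias = 0, threshold = 0.5) {
  p <- length(weights)
  structure(
    list(weights = weights, bias = bias, center = rep(0, p),
         scale = rep(1, p), decision_threshold = threshold),
    class = "nodule_classifier"
  )
}
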