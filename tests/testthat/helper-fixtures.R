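# Shared helpers: a minimal encoder spec that keeps tests fast, and tiny
# deterministic specimens.

tiny_spec <- function(...) {
  resolve_spec("mit-b0", utils::modifyList(
    list(hidden_dims = c(8L, 16L, 24L, 32L), depths = c(1L, 1L, 1L, 1L),
         attention_heads = c(1L, 2L, 4L, 8L), decoder_dim = 32L,
         dropout = 0),
    list(...)))
}

random_image <- function(H, W, seed = 1) {
  set.seed(seed)
  array(runif(H * W * 3), c(H, W, 3))
}

random_mask <- function(H, W, K = 12L, seed = 1) {
  set.seed(seed)
  matrix(sample(0:(K - 1L), H * W, replace = TRUE), H, W)
}

checker_specimen <- function(n = 64, seed = 1) {
  # two-class toy specimen: background ring, one central square of BCC
  mask <- matrix(11L, n, n)
  q <- (n %/% 4):(3 * n %/% 4)
  mask[q, q] <- 0L
  img <- encode_mask(mask)
  labeled_specimen(img, mask, id = sprintf("chk%d", seed))
}

# per-class pixel counts of a mask over the 12 classes
class_counts <- function(mask) {
  tabulate(mask + 1L, nbins = 12L)
}
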