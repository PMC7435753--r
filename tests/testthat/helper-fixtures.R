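# shared small fixtures

tiny_params <- function(...) {
  phantom_params(image_size = 64L, ...)
}

tiny_config <- function(...) {
  cascade_config(width_scale = 1 / 16, ...)
}

tiny_extractor <- function(seed = 5L) {
  perceptual_extractor(width_scale = 1 / 16, seed = seed)
}

rand_feature <- function(H, W, C, N = 1, seed = 1) {
  set.seed(seed)
  array(rnorm(H * W * C * N), dim = c(H, W, C, N))
}
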