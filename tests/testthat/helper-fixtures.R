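# Shared fixtures: published curves/conditions and small synthetic stacks.

flower_curve <- function() vulnerability_curve(4.89, -3.57, label = "flower")
leaf_curve <- function() vulnerability_curve(1.53, -6.48, label = "leaf")

heat_air <- function() air_state(40, 12)     # heat treatment: VPD ~6.5 kPa
growth_air <- function() air_state(20, 40)   # growth conditions: VPD ~1.4 kPa

# A tiny flat-background stack with one programmed step-change vessel.
one_event_stack <- function(h = 24, w = 16, n = 5, event_frame = 3,
                            rows = 10:12, cols = 5:12, step = 60) {
  frames <- lapply(seq_len(n), function(f) {
    m <- matrix(50, h, w)
    if (f >= event_frame) m[rows, cols] <- 50 + step
    m
  })
  image_stack(frames, timestamps = seq_len(n) * 60)
}

# Short scenario for cheap simulator tests (10 min ambient, 1 h heat).
short_scenario <- function(heat_s = 3600) {
  default_scenario(heat_s = heat_s, ambient_s = 600)
}
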