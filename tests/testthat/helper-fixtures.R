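# shared builders for tiny in-code fixtures

toy_course <- function(name = "toy", distance_km = 10, gain_m = 800,
                       loss_m = 900, scale = 1) {
  trail_course(
    name, distance_km * scale, gain_m * scale, loss_m * scale,
    data.frame(index = 1:4,
               start_cp = paste0("cp", 0:3), end_cp = paste0("cp", 1:4),
               distance_km = c(3, 2, 3, 2) * scale,
               gain_m = c(500, 50, 250, 0) * scale,
               loss_m = c(20, 500, 30, 350) * scale))
}

# five-section alternating course compatible with the fixture layout
toy_course5 <- function(scale = 1) {
  trail_course(
    "toy5", 30 * scale, 2000 * scale, 2100 * scale,
    data.frame(index = 1:5,
               start_cp = paste0("cp", 0:4), end_cp = paste0("cp", 1:5),
               distance_km = c(5, 4, 5, 4, 5) * scale,
               gain_m = c(800, 50, 600, 30, 500) * scale,
               loss_m = c(30, 900, 50, 800, 40) * scale))
}

# deterministic 5-checkpoint split table; times in decimal hours
toy_splits <- function(n = 6, modality = "4K", seed = 1) {
  set.seed(seed)
  base <- seq(1.5, 3.0, length.out = n)
  tibble::tibble(
    runner_id = sprintf("r%02d", seq_len(n)),
    modality = modality,
    sex = rep(c("male", "female"), length.out = n),
    cp_1 = base,
    cp_2 = base * 1.8,
    cp_3 = base * 2.5,
    cp_4 = base * 3.0,
    cp_5 = base * 3.6,
    finish = base * 5.0)
}

small_config <- function(n4 = 120, n8 = 40, seed = 11, ...) {
  synthetic_config(field_size = c(`4K` = n4, `8K` = n8), seed = seed, ...)
}
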