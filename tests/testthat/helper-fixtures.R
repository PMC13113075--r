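# Shared fixtures: all data is generated in code.

# small default-structure generator config (fewer animals for speed)
small_cfg <- function(n_animals = 8L, seed = 1L, ...) {
  generator_config(n_animals = n_animals, seed = seed, ...)
}

# hand-built minimal valid table (2 animals x 1 recording x 3 samples)
tiny_table <- function() {
  df <- data.frame(
    animal_id = rep(c("a1", "a2"), each = 3),
    sex = rep(c("female", "male"), each = 3),
    phase = "nursery", condition = "normal",
    recording_id = "r1", sample_index = rep(1:3, 2),
    energy = 1, duration = 0.5, amp_max = 0.5, amp_min = -0.5,
    intensity = 70, pitch = c(200, NA, 210, 190, 205, 195),
    f1 = 500, f2 = 1900, f3 = 2900, f4 = 4000,
    stringsAsFactors = FALSE)
  voc_table(df)
}

# balanced one-way layout (one phase, one condition, several recordings)
oneway_cfg <- function(n_animals = 20L, recs = 4L, seed = 1L,
                       sd_animal = 2, sd_resid = 3) {
  generator_config(
    n_animals = n_animals,
    availability = list(farrowing = "normal", nursery = "normal",
                        growing = "normal", finishing = "normal"),
    recordings_per_cell = recs,
    traits = list(intensity = list(sd_animal = sd_animal, sd_recording = 0,
                                   sd_resid = sd_resid)),
    seed = seed)
}
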