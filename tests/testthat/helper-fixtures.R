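# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one small phantom with all organs, for unit tests
tiny_phantom <- function() {
  cached("tiny_phantom", generate_phantom(
    phantom_spec(age = 10, canvas = c(96L, 64L, 64L), seed = 7L, id = "T01")
  ))
}

# the same phantom, preprocessed
tiny_case <- function() {
  cached("tiny_case", {
    ph <- tiny_phantom()
    preprocess_case(ph$volume, ph$labels, body = body_mask(ph$body))
  })
}

# the 16-phantom study cohort at 160 x 96 x 96, preprocessed once
e2e_prep <- function() {
  cached("e2e_prep", csiseg:::study_cases(16, 4, 1L))
}

# the scaled end-to-end study: one body organ (left kidney) and one head
# organ (left eye), basic U-Net
e2e_study <- function() {
  cached("e2e_study", run_phantom_study(
    n = 16, n_test = 4, seed = 1L, organs = c("kidney_l", "eye_l"),
    variants = "basic_unet", .prep = e2e_prep()
  ))
}

# mini-CT dataset matching the e2e kidney pipeline (reference ROIs, frozen
# clip and uniform size), for variant-contract checks on the same task
kidney_mini_dataset <- function() {
  cached("kidney_mini_dataset", {
    st <- e2e_study()
    pl <- st$pipelines$kidney_l
    out <- lapply(e2e_prep()$cases, function(case) {
      roi <- csiseg:::reference_localization(case, "kidney_l", pl$spec)$roi
      mini <- extract_mini_ct(case$volume, roi, "kidney_l",
                              pl$uniform_size, pl$clip)
      list(image = mini$voxels,
           mask = csiseg:::mask_to_mini(mask_of(case$labels, "kidney_l"), mini))
    })
    # the cohort itself is no longer needed once the minis exist
    rm(list = "e2e_prep", envir = .fixture_cache)
    out
  })
}

# a DSC record table with ages, for the statistics machinery
make_dsc_records <- function(n_patients = 27, models = c("basic_unet", "attn_unet"),
                             organs = c("kidney_l", "esophagus"), seed = 5) {
  withr::with_seed(seed, {
    ages <- runif(n_patients, 3, 18)
    do.call(rbind, lapply(models, function(m) {
      do.call(rbind, lapply(organs, function(o) {
        tibble::tibble(
          patient = sprintf("P%02d", seq_len(n_patients)), organ = o,
          model = m, cohort = "validation", age = ages,
          dsc = pmin(1, pmax(0, rnorm(n_patients, 0.85, 0.05)))
        )
      }))
    }))
  })
}
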