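# Lazily built, cached synthetic cohorts shared by the recovery and
# directional tests (built once per test run).

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, builder(), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# classifier trained once on two synthetic brightfield frames
egg_classifier <- function() {
  cached("egg_clf", function() {
    scenes <- lapply(c(101L, 102L), function(s)
      make_timelapse_2d(scene2d_params(seed = s)))
    imgs <- lapply(scenes, function(sc)
      get_channel(sc$frames[[1]], "brightfield"))
    labs <- lapply(c(101L, 102L), function(s)
      sparse_labels_from_mask(
        pmequant:::egg_mask_2d(scene2d_params(seed = s)), 600, seed = s))
    train_pixel_classifier(imgs, labs, seed = 11L)
  })
}

# per-egg NMI time courses for a cohort of synthetic eggs
kinetics_cohort <- function(n_eggs, k, seed_base) {
  clf <- egg_classifier()
  cfg <- analysis_config()
  ms <- list()
  for (i in seq_len(n_eggs)) {
    sc <- make_timelapse_2d(scene2d_params(seed = seed_base + i, k = k))
    ms <- c(ms, quantify_timelapse(sc$frames, clf, cfg))
  }
  build_timecourse(ms)
}

control_kinetics <- function() {
  cached("kin_control", function() kinetics_cohort(20, k = 1.0,
                                                   seed_base = 200L))
}

knockdown_kinetics <- function() {
  cached("kin_knockdown", function() kinetics_cohort(20, k = 0.1,
                                                     seed_base = 400L))
}

# shell-1..3 normalized-volume summary for one axoneme scene
shell13_sum <- function(seed, radial_weight = NULL) {
  p <- scene3d_params(seed = seed, shape = c(32, 96, 96), n_puncta = 400,
                      radial_weight = radial_weight)
  sc <- make_axoneme_volume_3d(p)
  axo <- get_channel(sc$stack, "axoneme") > 1600
  sh <- compute_shells(axo, p$spacing, K = 10, w = 1)
  obj <- label_and_filter(get_channel(sc$stack, "puncta") > 1600, p$spacing)
  obj <- filter_smallest_objects(obj, 0.40)
  pr <- shell_volume_profile(obj, sh)
  sum(pr$normalized_volume[1:3])
}

membrane_ratio_scene <- function(seed, fill) {
  p <- scene3d_params(seed = seed, shape = c(32, 96, 96), n_puncta = 0,
                      membrane_fill_fraction = fill)
  sc <- make_axoneme_volume_3d(p)
  axo <- get_channel(sc$stack, "axoneme") > 1600
  mem <- label_and_filter(get_channel(sc$stack, "membrane") > 1600,
                          p$spacing)
  membrane_axoneme_ratio(mem, axo, p$spacing)$ratio
}

vesicle_fraction_estimate <- function(seed, positive_fraction = 0.85,
                                      n_vesicles = 200) {
  p <- scene3d_params(seed = seed, shape = c(64, 192, 192),
                      n_vesicles = n_vesicles,
                      positive_fraction = positive_fraction)
  vs <- make_vesicle_volume_3d(p)
  cfg <- analysis_config()
  prim <- get_channel(vs$stack, "vesicle_primary")
  sec <- get_channel(vs$stack, "vesicle_secondary")
  obj <- label_and_filter(prim > p$background + p$intensity / 2, p$spacing,
                          min_size = cfg$vesicle_min_volume_um3,
                          units = "um3")
  rec <- measure_vesicles(obj, sec, p$spacing, cfg)
  list(estimate = classify_positive(rec)$fraction,
       truth = vs$manifest$true_positive_fraction,
       records = rec, objects = obj, stack = vs$stack)
}
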