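#' End-to-end experiment orchestration at desk scale
#'
#' Two study shapes mirror the method's evaluation design: an augmentation
#' study comparing six training-set variants (baseline, repeat sampling,
#' cutout, RBS, IS, mixed) on the same confounded synthetic dataset, and a
#' compression study comparing genetic-search pruning against equal-budget
#' random sampling, each followed by knowledge-distillation fine-tuning.
#' All stages derive their randomness from one global seed.
#'
#' @name pipeline
NULL

#' Desk-scale training preset
#'
#' The published recipe (momentum 0.9, cosine decay, early stop) with a
#' learning rate, batch size, epoch budget and patience suited to the
#' small synthetic benchmark.
#'
#' @param ... overrides passed to \code{\link{train_config}}.
#' @return A \code{train_config}.
#' @export
desk_train_config <- function(...) {
  args <- list(initial_lr = 0.025, batch_size = 32, early_stop_patience = 8,
               max_epochs = 18)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

#' Experiment configuration
#'
#' @param scene a \code{\link{scene_config}}.
#' @param mix list(is_fraction, rbs_fraction) augmentation mix.
#' @param train a \code{\link{train_config}}.
#' @param search a \code{\link{search_config}}.
#' @param kd a \code{\link{kd_config}}.
#' @param model_spec a \code{\link{classifier_spec}} (defaults to the desk
#'   backbone sized to the scene).
#' @param out_dir optional output directory for artifacts.
#' @param seed global seed propagated to every stage.
#' @return An \code{experiment_config} list.
#' @export
experiment_config <- function(scene = scene_config(),
                              mix = list(is_fraction = 1, rbs_fraction = 1),
                              train = desk_train_config(),
                              search = desk_search_config(),
                              kd = kd_config(train = desk_train_config()),
                              model_spec = NULL, out_dir = NULL, seed = 1) {
  if (is.null(model_spec))
    model_spec <- classifier_spec(num_classes = scene$n_species,
                                  input_side = scene$image_side)
  stop_if(model_spec$num_classes != scene$n_species,
          "model classes must match scene species")
  structure(list(scene = scene, mix = mix, train = train, search = search,
                 kd = kd, model_spec = model_spec, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Desk benchmark presets
#'
#' Two ready-made experiment configurations: \code{"augmentation"} is the
#' 96-pixel confounded-scene benchmark for the shortcut-learning studies
#' (the package defaults), and \code{"compression"} is a smaller 32-pixel,
#' higher-contrast, weakly confounded scene with a narrower backbone,
#' sized so pruning searches and distillation runs finish in minutes on
#' one CPU.
#'
#' @param kind \code{"augmentation"} or \code{"compression"}.
#' @param seed global seed.
#' @param ... overrides passed to \code{\link{experiment_config}}.
#' @return An \code{experiment_config}.
#' @export
desk_benchmark_config <- function(kind = c("augmentation", "compression"),
                                  seed = 1, ...) {
  kind <- match.arg(kind)
  if (kind == "augmentation") {
    experiment_config(scene = scene_config(seed = seed), seed = seed, ...)
  } else {
    scene <- scene_config(n_sites = 4, n_species = 4, image_side = 32,
                          confound_strength = 0.25,
                          instances_per_class = c(40, 20),
                          foreground_contrast = 0.6, fg_size_frac = 0.5,
                          seed = seed)
    experiment_config(
      scene = scene,
      model_spec = classifier_spec(c(8, 12, 16, 24), 1, num_classes = 4,
                                   input_side = 32),
      seed = seed, ...)
  }
}

reseed <- function(cfg, stage) {
  s <- derive_seed(cfg$seed, stage)
  cfg2 <- cfg
  cfg2$scene$seed <- derive_seed(s, 1)
  cfg2$train$seed <- derive_seed(s, 2)
  cfg2$search$seed <- derive_seed(s, 3)
  cfg2$kd$train$seed <- derive_seed(s, 4)
  cfg2
}

augment_variant <- function(method, data, mix, seed) {
  n_add <- round(((mix$is_fraction %||% 0) + (mix$rbs_fraction %||% 0)) *
                   length(data$train))
  records <- data$train$records
  N <- length(records)
  out <- switch(method,
    baseline = records,
    repeat_sampling = with_seed(derive_seed(seed, 101), {
      c(records, records[sample.int(N, n_add, replace = n_add > N)])
    }),
    cutout = with_seed(derive_seed(seed, 102), {
      picks <- sample.int(N, n_add, replace = n_add > N)
      c(records, lapply(picks, function(i) apply_cutout(records[[i]])))
    }),
    rbs = as_record_list(build_augmented_set(
      data$train, data$cutouts, data$backgrounds,
      mix = list(is_fraction = 0, rbs_fraction = n_add / N), seed = seed)),
    is = as_record_list(build_augmented_set(
      data$train, data$cutouts, data$backgrounds,
      mix = list(is_fraction = n_add / N, rbs_fraction = 0), seed = seed)),
    mixed = as_record_list(build_augmented_set(
      data$train, data$cutouts, data$backgrounds, mix = mix, seed = seed)),
    stop("unknown augmentation method: ", method))
  out
}

AUG_METHODS <- c("baseline", "repeat_sampling", "cutout", "rbs", "is",
                 "mixed")

#' Augmentation comparison study
#'
#' Trains one model per training-set variant on the same synthetic
#' confounded dataset and reports accuracy on the decorrelated test set
#' plus mean FRoH per method. Every non-baseline variant adds the same
#' number of records (the mixed method splits its additions between IS
#' and RBS), so methods differ in kind, not amount, of augmentation.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param methods subset of the six method names.
#' @param data optional pre-generated \code{\link{generate_dataset}}
#'   output (regenerated from \code{cfg$scene} when NULL).
#' @param with_froh compute FRoH per method (Grad-CAM over the test set).
#' @param progress print progress.
#' @return list(table, models, data) of class \code{aug_study}; the table
#'   has one row per method with ACCcls and FRoH.
#' @export
run_augmentation_study <- function(cfg = experiment_config(),
                                   methods = AUG_METHODS, data = NULL,
                                   with_froh = TRUE, progress = FALSE) {
  cfg <- reseed(cfg, 1)
  if (is.null(data)) data <- generate_dataset(cfg$scene)
  rows <- list(); models <- list()
  for (m in methods) {
    if (progress) message("training variant: ", m)
    recs <- augment_variant(m, data, cfg$mix, cfg$seed)
    model <- build_classifier(cfg$model_spec, seed = derive_seed(cfg$seed, 5))
    model <- train_classifier(model, recs, data$test$records, cfg$train,
                              progress = FALSE)
    ev <- evaluate_model(model, data$test, with_froh = with_froh)
    tr_acc <- acc_cls(predict(model, recs)$labels, records_labels(recs))
    rows[[m]] <- data.frame(method = m, n_train = length(recs),
                            train_acc = tr_acc, acc_cls = ev$acc,
                            froh = ev$froh %||% NA_real_)
    models[[m]] <- model
  }
  out <- structure(list(table = do.call(rbind, rows), models = models,
                        data = data, cfg = cfg),
                   class = "aug_study")
  if (!is.null(cfg$out_dir)) save_study_table(out$table, cfg$out_dir,
                                              "augmentation_study.csv")
  out
}

#' @export
print.aug_study <- function(x, ...) {
  cat("Augmentation study (decorrelated test set):\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compression comparison study
#'
#' Trains (or reuses) a teacher, runs the genetic pruning search and an
#' equal-budget random-sampling search at the configured MAC band,
#' fine-tunes each best student with the configured distillation method,
#' and reports accuracy, parameter and MAC counts per method alongside
#' the per-generation fitness histories.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param data optional pre-generated dataset.
#' @param teacher optional pre-trained teacher \code{trap_cnn}.
#' @param progress print progress.
#' @return list(table, ga, rs, teacher, students) of class
#'   \code{compress_study}.
#' @export
run_compression_study <- function(cfg = experiment_config(), data = NULL,
                                  teacher = NULL, progress = FALSE) {
  cfg <- reseed(cfg, 2)
  if (is.null(data)) data <- generate_dataset(cfg$scene)
  if (is.null(teacher)) {
    if (progress) message("training teacher")
    teacher <- build_classifier(cfg$model_spec,
                                seed = derive_seed(cfg$seed, 6))
    teacher <- train_classifier(teacher, data$train, data$test, cfg$train)
  }
  scfg <- cfg$search
  if (progress) message("genetic search")
  ga <- ga_search(teacher, data$train, data$test, scfg)
  if (progress) message("random-sampling baseline (equal budget)")
  rs <- random_search(teacher, data$train, data$test, scfg,
                      n_evals = ga$n_evals)
  finetune <- function(student) {
    finetune_with_kd(student, teacher, data$train, data$test, cfg$kd)
  }
  if (progress) message("distillation fine-tuning")
  ga_ft <- finetune(ga$best_model)
  rs_ft <- finetune(rs$best_model)
  acc_of <- function(m) evaluate_model(m, data$test)$acc
  base_macs <- count_macs(teacher$arch)$macs_total
  row <- function(method, model, pruned_acc = NA) {
    data.frame(method = method, acc = acc_of(model), pruned_acc = pruned_acc,
               params = count_params(model$arch)$params_total,
               macs = count_macs(model$arch)$macs_total,
               mac_ratio = count_macs(model$arch)$macs_total / base_macs)
  }
  tab <- rbind(row("teacher", teacher),
               row("random_sampling", rs_ft, rs$best$n),
               row("ga_abn", ga_ft, ga$best$n))
  out <- structure(list(table = tab, ga = ga, rs = rs, teacher = teacher,
                        students = list(ga = ga_ft, random = rs_ft),
                        cfg = cfg),
                   class = "compress_study")
  if (!is.null(cfg$out_dir)) {
    save_study_table(tab, cfg$out_dir, "compression_study.csv")
    save_study_table(ga$history, cfg$out_dir, "ga_history.csv")
    save_study_table(rs$history, cfg$out_dir, "random_history.csv")
    jsonlite::write_json(as.list(ga$best$genome),
                         file.path(cfg$out_dir, "best_genome.json"),
                         auto_unbox = TRUE, digits = NA)
    write_hash_manifest(cfg$out_dir)
  }
  out
}

#' @export
print.compress_study <- function(x, ...) {
  cat("Compression study (MAC band ",
      sprintf("%.0f +/- %.0f%%):\n", 100 * x$cfg$search$compression_target,
              100 * x$cfg$search$band_halfwidth), sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

save_study_table <- function(tab, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(dir, name), row.names = FALSE)
}

#' Stratified train/test split
#'
#' Splits a record list by class in the given proportion (the evaluation
#' design's 7:3 by default), stratified so every class keeps the ratio.
#'
#' @param records record list or \code{trap_dataset}.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @return list(train, test) of record lists.
#' @export
stratified_split <- function(records, train_frac = 0.7, seed = 1) {
  recs <- as_record_list(records)
  y <- records_labels(recs)
  tr <- integer(0)
  with_seed(derive_seed(seed, 91), {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      k <- round(train_frac * length(idx))
      tr <- c(tr, sample(idx, k))
    }
  })
  list(train = recs[sort(tr)], test = recs[setdiff(seq_along(recs), tr)])
}

#' Published full-scale reference figures
#'
#' Headline figures of the full-scale (six-species camera-trap, 448x448
#' residual-network) study that this package reproduces in shape at desk
#' scale: accuracy/params/MACs of the teacher and of the two pruned
#' models at the 50 +/- 5\% band, and accuracies of the distillation
#' fine-tuning variants. Used to recompute the derived compression and
#' fine-tuning deltas; the desk-scale synthetic benchmark does not
#' reproduce these absolute values.
#'
#' @return list of data.frames: \code{pruning} and \code{distillation}.
#' @export
reference_benchmarks <- function() {
  list(
    pruning = data.frame(
      method = c("teacher", "random_sampling", "ga_abn"),
      acc = c(91.23, 84.90, 86.50),
      params_M = c(23.52, 10.65, 10.01),
      flops_G = c(16.48, 8.85, 8.89)),
    distillation = data.frame(
      method = c("pruned_baseline", "kd_skl", "kd_hkl", "kd_mse"),
      acc = c(86.50, 87.72, 86.99, 88.38)))
}

#' Compression and fine-tuning deltas from the reference figures
#'
#' Recomputes, from \code{\link{reference_benchmarks}}, the derived
#' quantities the full-scale study reports: the percentage reductions in
#' parameters and MACs of the genetically pruned model relative to the
#' teacher, the accuracy drop of pruning, and the accuracy gain of
#' MSE-distillation fine-tuning over the un-fine-tuned pruned model.
#'
#' @return named list of percentages (one decimal where the reference
#'   prints one): \code{param_reduction_pct}, \code{flop_reduction_pct},
#'   \code{accuracy_drop_pct}, \code{kd_mse_gain_pct}.
#' @export
compression_deltas <- function() {
  rb <- reference_benchmarks()
  p <- rb$pruning; d <- rb$distillation
  teach <- p[p$method == "teacher", ]
  ga <- p[p$method == "ga_abn", ]
  list(
    param_reduction_pct = round(100 * (1 - ga$params_M / teach$params_M), 1),
    flop_reduction_pct = round(100 * (1 - ga$flops_G / teach$flops_G), 1),
    accuracy_drop_pct = teach$acc - ga$acc,
    kd_mse_gain_pct = d$acc[d$method == "kd_mse"] -
      d$acc[d$method == "pruned_baseline"])
}
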