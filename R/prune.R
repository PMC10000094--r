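#' Structured channel pruning by genetic search with adaptive BN
#'
#' A candidate sub-network ("genome") assigns each prunable channel group
#' a keep ratio from the grid 0.1, 0.2, ..., 1.0, constrained so the
#' sub-network's multiply--accumulate count stays inside a band around the
#' compression target (e.g. 50 +/- 5\%). Each candidate is materialized by
#' keeping the teacher channels with the largest L1 filter norms, its
#' batch-normalization statistics are recomputed from calibration batches
#' (adaptive BN: batch mean and unbiased variance, averaged over batches),
#' and its fitness is computed from validation accuracy and parameter
#' count. A genetic loop (selection of the fittest, uniform crossover,
#' per-gene mutation, elitism) evolves the population until the total
#' fitness stalls.
#'
#' @name prune
NULL

PRUNE_GRID <- seq(0.1, 1, by = 0.1)

#' Genetic-search configuration
#'
#' The published search used a population of 100 with the top 20 kept;
#' \code{\link{desk_search_config}} scales this to desk size. The fitness
#' formula is selectable: \code{"literal_product"} scores
#' \code{n * (p / p0)} (accuracy times relative size, the printed form)
#' and \code{"accuracy_per_size"} scores \code{n / (p / p0)} (accuracy
#' per unit size); both are exposed because the two readings reward
#' opposite size preferences inside the band.
#'
#' @param compression_target target MAC ratio of student to teacher.
#' @param band_halfwidth allowed deviation from the target.
#' @param population_size offspring per generation.
#' @param parents_kept survivors per generation.
#' @param mutation_rate per-gene resampling probability.
#' @param recal_batches calibration mini-batches for adaptive BN.
#' @param batch_size calibration batch size.
#' @param fitness_form \code{"literal_product"} or
#'   \code{"accuracy_per_size"}.
#' @param convergence_tol relative change of total population fitness
#'   regarded as a stall.
#' @param convergence_patience consecutive stalled generations before
#'   stopping.
#' @param max_generations hard cap.
#' @param p0 teacher parameter count (filled in by the search if NULL).
#' @param retry_budget rejection-sampling budget for band-valid genomes.
#' @param seed RNG seed.
#' @return A \code{search_config} list.
#' @export
search_config <- function(compression_target = 0.5, band_halfwidth = 0.05,
                          population_size = 100, parents_kept = 20,
                          mutation_rate = 0.1, recal_batches = 30,
                          batch_size = 32,
                          fitness_form = "literal_product",
                          convergence_tol = 1e-3,
                          convergence_patience = 3,
                          max_generations = 30, p0 = NULL,
                          retry_budget = 2000, seed = 1) {
  stop_if(compression_target - band_halfwidth <= 0 ||
          compression_target > 1,
          "compression band must lie inside (0, 1]")
  stop_if(parents_kept >= population_size,
          "parents_kept must be smaller than population_size")
  stop_if(!fitness_form %in% c("literal_product", "accuracy_per_size"),
          "unknown fitness_form")
  structure(list(compression_target = compression_target,
                 band_halfwidth = band_halfwidth,
                 population_size = as.integer(population_size),
                 parents_kept = as.integer(parents_kept),
                 mutation_rate = mutation_rate,
                 recal_batches = as.integer(recal_batches),
                 batch_size = as.integer(batch_size),
                 fitness_form = fitness_form,
                 convergence_tol = convergence_tol,
                 convergence_patience = as.integer(convergence_patience),
                 max_generations = as.integer(max_generations),
                 p0 = p0, retry_budget = as.integer(retry_budget),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Desk-scale search preset (12 parents, 36 offspring)
#'
#' @param ... overrides passed to \code{\link{search_config}}.
#' @return A \code{search_config}.
#' @export
desk_search_config <- function(...) {
  args <- list(population_size = 36, parents_kept = 12, recal_batches = 8,
               max_generations = 15)
  args[names(list(...))] <- list(...)
  do.call(search_config, args)
}

genome_key <- function(genome) paste(sprintf("%.1f", genome), collapse = ",")

mac_ratio <- function(arch, genome, base_macs) {
  count_macs(apply_genome(arch, genome))$macs_total / base_macs
}

#' Sample a band-valid prune genome
#'
#' Uniform per-group sampling from the keep-ratio grid, rejected until the
#' pruned architecture's MAC ratio falls inside
#' \code{compression_target +/- band_halfwidth}.
#'
#' @param arch teacher \code{arch_descriptor}.
#' @param cfg a \code{\link{search_config}}.
#' @return named numeric vector of keep ratios.
#' @export
sample_genome <- function(arch, cfg) {
  groups <- prune_groups(arch)
  base <- count_macs(arch)$macs_total
  lo <- cfg$compression_target - cfg$band_halfwidth
  hi <- cfg$compression_target + cfg$band_halfwidth
  closest <- NULL; closest_gap <- Inf
  for (i in seq_len(cfg$retry_budget)) {
    g <- stats::setNames(sample(PRUNE_GRID, length(groups), replace = TRUE),
                         groups)
    r <- mac_ratio(arch, g, base)
    if (r >= lo && r <= hi) return(g)
    gap <- min(abs(r - lo), abs(r - hi))
    if (gap < closest_gap) { closest_gap <- gap; closest <- r }
  }
  stop(sprintf(paste0("no genome found in MAC band [%.2f, %.2f] after %d ",
                      "tries (closest achieved ratio: %.3f)"),
               lo, hi, cfg$retry_budget, closest), call. = FALSE)
}

# Per-group kept-channel indices in the teacher: rank output channels by
# the summed L1 norm of their filters across the group's convolutions.
kept_channels <- function(teacher, genome) {
  spec <- teacher$spec
  keeps <- list()
  conv_i <- 0
  scores <- rep(list(0), length(spec$stage_widths))
  for (ly in teacher$layers) {
    if (ly$type == "conv") {
      conv_i <- conv_i + 1
      st <- conv_stage(spec, conv_i)
      s <- colSums(abs(ly$W))
      scores[[st]] <- (scores[[st]] %||% 0) + s
    }
  }
  for (st in seq_along(spec$stage_widths)) {
    g <- sprintf("s%d", st)
    w <- spec$stage_widths[st]
    k <- max(1, round_half_up(genome[[g]] * w))
    ord <- order(-scores[[st]], seq_len(w))    # ties: lower index first
    keeps[[g]] <- sort(ord[seq_len(k)])
  }
  keeps
}

# Which stage the i-th conv layer of a stage CNN belongs to.
conv_stage <- function(spec, conv_i) {
  cum <- cumsum(spec$blocks_per_stage)
  which(conv_i <= cum)[1]
}

#' Materialize a pruned student from a teacher
#'
#' For each prune group, keeps the channels with the largest L1 filter
#' norms (summed across the group's convolutions) and slices every
#' dependent tensor -- following convolutions' input channels, BN
#' parameters and running statistics, and the classifier head's input --
#' consistently. The all-ones genome returns a student whose forward pass
#' is bitwise identical to the teacher's.
#'
#' @param teacher a trained \code{trap_cnn}.
#' @param genome named keep-ratio vector over the teacher's prune groups.
#' @return An un-recalibrated student \code{trap_cnn}.
#' @export
materialize_student <- function(teacher, genome) {
  genome <- unlist(genome)
  spec <- teacher$spec
  keeps <- kept_channels(teacher, genome)
  new_widths <- vapply(keeps, length, integer(1))
  sspec <- classifier_spec(stage_widths = new_widths,
                           blocks_per_stage = spec$blocks_per_stage,
                           num_classes = spec$num_classes,
                           input_side = spec$input_side,
                           with_residual = spec$with_residual)
  layers <- teacher$layers
  conv_i <- 0
  keep_in <- seq_len(3)                        # input channels all kept
  K2 <- 9
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      conv_i <- conv_i + 1
      st <- conv_stage(spec, conv_i)
      keep_out <- keeps[[sprintf("s%d", st)]]
      rows <- as.vector(vapply(keep_in,
                               function(c) ((c - 1) * K2 + 1):(c * K2),
                               integer(K2)))
      layers[[i]]$W <- ly$W[rows, keep_out, drop = FALSE]
      keep_in <- keep_out
    } else if (ly$type == "bn") {
      for (f in c("gamma", "beta", "run_mean", "run_var"))
        layers[[i]][[f]] <- ly[[f]][keep_in]
    } else if (ly$type == "fc") {
      layers[[i]]$W <- ly$W[keep_in, , drop = FALSE]
    }
  }
  structure(list(spec = sspec, layers = layers,
                 input_side = sspec$input_side,
                 num_classes = sspec$num_classes,
                 arch = as_arch_descriptor(sspec),
                 genome = genome, seed = teacher$seed),
            class = "trap_cnn")
}

#' Adaptive batch-normalization recalibration
#'
#' Replaces every BN layer's inference statistics with the batch mean and
#' unbiased (n - 1 denominator) variance of its pre-normalization
#' activations, averaged over \code{recal_batches} mini-batches of the
#' calibration data, with all weights frozen. Variances are floored at
#' 1e-5 so degenerate (constant) batches cannot produce a zero
#' denominator. Deterministic under \code{seed}. When \code{genome} is
#' supplied the teacher is pruned first via
#' \code{\link{materialize_student}}.
#'
#' @param model a \code{trap_cnn} (teacher if \code{genome} given).
#' @param calibration a \code{trap_dataset} or record list.
#' @param recal_batches number of calibration mini-batches (>= 1).
#' @param batch_size mini-batch size.
#' @param seed RNG seed for batch selection.
#' @param genome optional prune genome to materialize first.
#' @return The recalibrated \code{trap_cnn}.
#' @export
recalibrate_bn <- function(model, calibration, recal_batches = 30,
                           batch_size = 32, seed = 1, genome = NULL) {
  stop_if(recal_batches < 1, "recal_batches must be >= 1")
  if (!is.null(genome)) model <- materialize_student(model, genome)
  records <- as_record_list(calibration)
  stop_if(length(records) == 0, "calibration data must be non-empty")
  X <- records_to_tensor(records, model$input_side)
  n <- length(records)
  sums <- list()
  with_seed(derive_seed(seed, 53), {
    for (b in seq_len(recal_batches)) {
      idx <- sample.int(n, min(batch_size, n))
      fwd <- net_forward(model, X[, , idx, drop = FALSE], training = TRUE,
                         collect_bn = TRUE)
      for (nm in names(fwd$bn_stats)) {
        st <- fwd$bn_stats[[nm]]
        sums[[nm]] <- list(mean = (sums[[nm]]$mean %||% 0) + st$mean,
                           var = (sums[[nm]]$var %||% 0) + st$var)
      }
    }
  })
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "bn") {
      model$layers[[i]]$run_mean <- sums[[ly$name]]$mean / recal_batches
      model$layers[[i]]$run_var <-
        pmax(sums[[ly$name]]$var / recal_batches, 1e-5)
    }
  }
  model
}

#' Fitness of an evaluated sub-network
#'
#' @param model a recalibrated student \code{trap_cnn}.
#' @param valid validation data.
#' @param cfg a \code{\link{search_config}} with \code{p0} set.
#' @return An \code{individual}: list(genome, n, p, f, macs).
#' @export
evaluate_fitness <- function(model, valid, cfg) {
  stop_if(is.null(cfg$p0) || cfg$p0 == 0, "cfg$p0 (teacher params) missing")
  pr <- predict(model, valid)
  n <- acc_cls(pr$labels, records_labels(as_record_list(valid)))
  p <- count_params(model$arch)$params_total
  f <- fitness_value(n, p, cfg$p0, cfg$fitness_form)
  structure(list(genome = model$genome, n = n, p = p, f = f,
                 macs = count_macs(model$arch)$macs_total),
            class = "individual")
}

#' Fitness formula
#'
#' @param n validation accuracy in [0, 1].
#' @param p sub-network parameter count.
#' @param p0 teacher parameter count.
#' @param form \code{"literal_product"} (n * p/p0) or
#'   \code{"accuracy_per_size"} (n / (p/p0)).
#' @return fitness value.
#' @export
fitness_value <- function(n, p, p0, form = "literal_product") {
  switch(form,
         literal_product = n * (p / p0),
         accuracy_per_size = n / (p / p0),
         stop("unknown fitness form"))
}

#' Breed a new population from selected parents
#'
#' Uniform per-gene crossover of two distinct uniformly drawn parents,
#' then per-gene mutation (resampling from the keep-ratio grid with
#' probability \code{mutation_rate}); every offspring is re-checked
#' against the MAC band with bounded resampling.
#'
#' @param parents list of \code{individual}s (or genomes).
#' @param arch teacher descriptor.
#' @param cfg a \code{\link{search_config}}.
#' @return list of \code{population_size} band-valid genomes.
#' @export
evolve_generation <- function(parents, arch, cfg) {
  stop_if(length(parents) < 2, "need at least two parents")
  genomes <- lapply(parents, function(p) if (is.list(p)) p$genome else p)
  base <- count_macs(arch)$macs_total
  lo <- cfg$compression_target - cfg$band_halfwidth
  hi <- cfg$compression_target + cfg$band_halfwidth
  ng <- length(genomes[[1]])
  offspring <- vector("list", cfg$population_size)
  for (k in seq_len(cfg$population_size)) {
    ok <- FALSE
    for (try in seq_len(cfg$retry_budget)) {
      pick <- sample.int(length(genomes), 2)
      a <- genomes[[pick[1]]]; b <- genomes[[pick[2]]]
      take_a <- stats::runif(ng) < 0.5
      child <- ifelse(take_a, a, b)
      mut <- stats::runif(ng) < cfg$mutation_rate
      if (any(mut)) child[mut] <- sample(PRUNE_GRID, sum(mut),
                                         replace = TRUE)
      names(child) <- names(a)
      r <- mac_ratio(arch, child, base)
      if (r >= lo && r <= hi) { offspring[[k]] <- child; ok <- TRUE; break }
    }
    stop_if(!ok, "could not breed a band-valid offspring within budget")
  }
  offspring
}

# Evaluate one genome end to end (materialize, adaptive BN, fitness),
# memoized on the genome so elitism never re-pays evaluation cost.
make_evaluator <- function(teacher, calib, valid, cfg) {
  cache <- new.env(parent = emptyenv())
  n_evals <- 0
  eval_genome <- function(genome) {
    key <- genome_key(genome)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    student <- recalibrate_bn(teacher, calib,
                              recal_batches = cfg$recal_batches,
                              batch_size = cfg$batch_size,
                              seed = derive_seed(cfg$seed, 61), genome = genome)
    ind <- evaluate_fitness(student, valid, cfg)
    cache[[key]] <- ind
    n_evals <<- n_evals + 1
    ind
  }
  list(eval = eval_genome, evals = function() n_evals)
}

#' Genetic search for an optimal pruned sub-network
#'
#' Alternates sampling/breeding, student materialization, adaptive-BN
#' recalibration, fitness evaluation and selection of the fittest
#' \code{parents_kept}, with parents carried into the next evaluated pool
#' (elitism, so the best fitness is non-decreasing). Stops when the
#' relative change of the population's total fitness stays below
#' \code{convergence_tol} for \code{convergence_patience} consecutive
#' generations, or at \code{max_generations}.
#'
#' @param teacher a trained \code{trap_cnn}.
#' @param calib calibration data (training records).
#' @param valid validation data.
#' @param cfg a \code{\link{search_config}}; \code{p0} defaults to the
#'   teacher's parameter count.
#' @return list(best, history, parents, n_evals, best_model) of class
#'   \code{ga_search}.
#' @export
ga_search <- function(teacher, calib, valid, cfg = desk_search_config()) {
  if (is.null(cfg$p0)) cfg$p0 <- count_params(teacher$arch)$params_total
  arch <- teacher$arch
  ev <- make_evaluator(teacher, calib, valid, cfg)
  hist <- list()
  stall <- 0
  prev_total <- NULL
  best <- NULL
  parents <- NULL
  gen <- 0
  repeat {
    pop <- with_seed(derive_seed(cfg$seed, 71, gen), {
      if (gen == 0)
        lapply(seq_len(cfg$population_size), function(i) sample_genome(arch, cfg))
      else
        evolve_generation(parents, arch, cfg)
    })
    inds <- lapply(pop, ev$eval)
    pool <- c(parents, inds)
    fs <- vapply(pool, function(i) i$f, numeric(1))
    ord <- order(-fs)
    parents <- pool[ord[seq_len(min(cfg$parents_kept, length(pool)))]]
    if (is.null(best) || parents[[1]]$f > best$f) best <- parents[[1]]
    total <- sum(vapply(inds, function(i) i$f, numeric(1)))
    hist[[gen + 1]] <- data.frame(
      generation = gen, best_f = best$f, mean_f = mean(fs),
      total_f = total, best_acc = best$n, best_params = best$p,
      best_macs = best$macs)
    if (!is.null(prev_total)) {
      rel <- abs(total - prev_total) / max(abs(prev_total), 1e-12)
      stall <- if (rel < cfg$convergence_tol) stall + 1 else 0
    }
    prev_total <- total
    gen <- gen + 1
    if (stall >= cfg$convergence_patience || gen > cfg$max_generations)
      break
  }
  best_model <- recalibrate_bn(teacher, calib,
                               recal_batches = cfg$recal_batches,
                               batch_size = cfg$batch_size,
                               seed = derive_seed(cfg$seed, 61),
                               genome = best$genome)
  structure(list(best = best, history = do.call(rbind, hist),
                 parents = parents, n_evals = ev$evals(),
                 best_model = best_model, cfg = cfg),
            class = "ga_search")
}

#' @export
print.ga_search <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("GA pruning search: %d generations, %d evaluations\n",
                     "  best fitness %.4f (acc %.3f, params %s, MAC ratio ",
                     "in-band)\n"),
              nrow(h), x$n_evals, x$best$f, x$best$n,
              format(x$best$p, big.mark = ",")))
  invisible(x)
}

#' Plot fitness history of a search
#'
#' @param x a \code{ga_search} (or \code{random_search}) result.
#' @param ... passed to \code{plot}.
#' @export
plot.ga_search <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best_f, type = "b", pch = 16,
                 xlab = "generation", ylab = "fitness",
                 ylim = range(c(h$best_f, h$mean_f)), ...)
  graphics::lines(h$generation, h$mean_f, lty = 2)
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' Random-sampling pruning baseline
#'
#' Samples \code{n_evals} band-valid genomes and evaluates each with the
#' same materialization and adaptive-BN procedure as the genetic search
#' (no selection mechanism). The comparison baseline for the search.
#'
#' @param teacher a trained \code{trap_cnn}.
#' @param calib,valid calibration and validation data.
#' @param cfg a \code{\link{search_config}}.
#' @param n_evals evaluation budget (default: one GA-equivalent budget of
#'   \code{max_generations * population_size}).
#' @return list(best, history, n_evals, best_model) of class
#'   \code{c("random_search", "ga_search")}.
#' @export
random_search <- function(teacher, calib, valid, cfg = desk_search_config(),
                          n_evals = cfg$max_generations *
                            cfg$population_size) {
  if (is.null(cfg$p0)) cfg$p0 <- count_params(teacher$arch)$params_total
  arch <- teacher$arch
  ev <- make_evaluator(teacher, calib, valid, cfg)
  best <- NULL
  hist <- list()
  for (k in seq_len(n_evals)) {
    g <- with_seed(derive_seed(cfg$seed, 83, k), sample_genome(arch, cfg))
    ind <- ev$eval(g)
    if (is.null(best) || ind$f > best$f) best <- ind
    if (k %% cfg$population_size == 0 || k == n_evals) {
      hist[[length(hist) + 1]] <- data.frame(
        generation = length(hist), best_f = best$f, mean_f = NA,
        total_f = NA, best_acc = best$n, best_params = best$p,
        best_macs = best$macs)
    }
  }
  best_model <- recalibrate_bn(teacher, calib,
                               recal_batches = cfg$recal_batches,
                               batch_size = cfg$batch_size,
                               seed = derive_seed(cfg$seed, 61),
                               genome = best$genome)
  structure(list(best = best, history = do.call(rbind, hist),
                 n_evals = ev$evals(), best_model = best_model, cfg = cfg),
            class = c("random_search", "ga_search"))
}
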