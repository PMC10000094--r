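#' Knowledge-distillation fine-tuning of a pruned student
#'
#' The pruned student is fine-tuned against the frozen teacher. Three
#' supervision signals are available: \code{mse} (mean squared difference
#' of the two models' output probability distributions -- the primary
#' method), \code{soft_kl} (KL divergence of the student from the
#' teacher's soft probabilities, optionally temperature-softened), and
#' \code{hard_kl} (cross-entropy against the teacher's argmax pseudo
#' labels). The training loss is cross-entropy on the ground truth plus
#' \code{lambda} times the distillation loss.
#'
#' @name distill
NULL

#' Distillation configuration
#'
#' @param method \code{"mse"}, \code{"soft_kl"} or \code{"hard_kl"}.
#' @param lambda non-negative weight of the distillation term.
#' @param temperature softening temperature (> 0; \code{soft_kl} only).
#' @param on_logits compute the MSE on raw logits instead of
#'   probabilities (sensitivity check; default FALSE).
#' @param train a \code{\link{train_config}} for the fine-tuning loop.
#' @return A \code{kd_config} list.
#' @export
kd_config <- function(method = "mse", lambda = 1, temperature = 1,
                      on_logits = FALSE, train = train_config()) {
  stop_if(!method %in% c("mse", "soft_kl", "hard_kl"), "unknown KD method")
  stop_if(lambda < 0, "lambda must be non-negative")
  stop_if(temperature <= 0, "temperature must be positive")
  structure(list(method = method, lambda = lambda,
                 temperature = temperature, on_logits = isTRUE(on_logits),
                 train = train),
            class = "kd_config")
}

clip_prob <- function(p) pmin(pmax(p, 1e-12), 1)

#' Knowledge-distillation loss
#'
#' \describe{
#' \item{mse}{mean over the batch and classes of the squared difference
#'   of student and teacher probability vectors.}
#' \item{soft_kl}{mean KL(teacher || student) of temperature-softened
#'   distributions, scaled by temperature^2.}
#' \item{hard_kl}{cross-entropy of the student probabilities against the
#'   teacher's argmax one-hot targets (KL up to the zero entropy of a
#'   one-hot distribution).}
#' }
#' All three are non-negative and zero-minimized at student = teacher
#' (exactly for mse and soft_kl).
#'
#' @param student_probs matrix of student probability rows.
#' @param teacher_probs matrix of teacher probability rows.
#' @param cfg a \code{\link{kd_config}}.
#' @param teacher_labels optional teacher hard labels (argmax of
#'   \code{teacher_probs} when omitted; \code{hard_kl} only).
#' @return scalar loss.
#' @export
kd_loss <- function(student_probs, teacher_probs, cfg = kd_config(),
                    teacher_labels = NULL) {
  stop_if(!all(dim(student_probs) == dim(teacher_probs)),
          "student and teacher class counts or batch sizes differ")
  N <- nrow(student_probs); C <- ncol(student_probs)
  if (cfg$method == "mse") {
    mean((student_probs - teacher_probs)^2)
  } else if (cfg$method == "soft_kl") {
    Ts <- cfg$temperature
    pt <- soften(teacher_probs, Ts)
    ps <- clip_prob(soften(student_probs, Ts))
    Ts^2 * sum(pt * (log(clip_prob(pt)) - log(ps))) / N
  } else {
    lab <- teacher_labels %||% max.col(teacher_probs, ties.method = "first")
    -mean(log(clip_prob(student_probs[cbind(seq_len(N), lab)])))
  }
}

# Temperature-soften a probability distribution: softmax(log p / T).
soften <- function(p, Ts) {
  if (Ts == 1) return(p)
  lp <- log(clip_prob(p)) / Ts
  softmax(lp)
}

# Gradient of lambda * kd term w.r.t. student LOGITS (mean over batch),
# used inside the fine-tuning loop.
kd_grad_logits <- function(student_logits, teacher_probs, cfg) {
  N <- nrow(student_logits); C <- ncol(student_logits)
  ps <- softmax(student_logits)
  if (cfg$method == "mse") {
    g <- 2 * (ps - teacher_probs) / (N * C)
    dz <- ps * (g - rowSums(g * ps))
  } else if (cfg$method == "soft_kl") {
    Ts <- cfg$temperature
    pt <- soften(teacher_probs, Ts)
    ps_t <- softmax(student_logits / Ts)
    dz <- Ts * (ps_t - pt) / N                 # T^2 * (1/T) chain factor
  } else {
    lab <- max.col(teacher_probs, ties.method = "first")
    dz <- ps
    dz[cbind(seq_len(N), lab)] <- dz[cbind(seq_len(N), lab)] - 1
    dz <- dz / N
  }
  dz
}

#' Fine-tune a student with knowledge distillation
#'
#' The teacher is frozen; the student is trained on
#' \code{CE(student, labels) + lambda * kd_loss(student, teacher)} with
#' the optimizer, schedule and early stopping of \code{cfg$train}. The
#' history logs both loss components per epoch.
#'
#' @param student a \code{trap_cnn} (e.g. a recalibrated pruned model).
#' @param teacher a trained \code{trap_cnn} with the same class count.
#' @param train,valid training and validation data.
#' @param cfg a \code{\link{kd_config}}.
#' @param progress print per-epoch progress.
#' @return The fine-tuned student with history attached.
#' @export
finetune_with_kd <- function(student, teacher, train, valid,
                             cfg = kd_config(), progress = FALSE) {
  stop_if(student$num_classes != teacher$num_classes,
          "student and teacher class counts differ")
  train_records <- as_record_list(train)
  valid_records <- as_record_list(valid)
  Xtr <- records_to_tensor(train_records, student$input_side)
  ytr <- records_labels(train_records)
  grad_fn <- function(logits, idx) {
    ce <- ce_grad(logits, ytr[idx])
    tfwd <- net_forward(teacher, Xtr[, , idx, drop = FALSE],
                        training = FALSE)
    tp <- softmax(tfwd$logits)
    sp <- softmax(logits)
    if (cfg$method == "mse" && cfg$on_logits) {
      # sensitivity variant: match raw logits instead of probabilities
      kd <- mean((logits - tfwd$logits)^2)
      dkd <- 2 * (logits - tfwd$logits) / length(logits)
    } else {
      kd <- kd_loss(sp, tp, cfg)
      dkd <- kd_grad_logits(logits, tp, cfg)
    }
    list(loss = ce$loss + cfg$lambda * kd,
         components = list(ce_loss = ce$loss, kd_loss = kd),
         dlogits = ce$dlogits + cfg$lambda * dkd)
  }
  sgd_train(student, train_records, valid_records, cfg$train, grad_fn,
            progress)
}
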