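#' Adaptation experiment design
#'
#' The nontarget-distribution adaptation design: 8 blocks of 72 trials
#' (576 total) of 4-item arrays. Block 1 is preadaptation and block 8
#' postadaptation (uniform nontargets); blocks 2--7 are adaptation
#' blocks whose nontargets follow a manipulated bimodal distribution.
#' Targets are sampled uniformly in every block. Spatial positions are
#' not modeled (no in-scope analysis depends on location).
#'
#' @param n_blocks number of blocks (default 8)
#' @param trials_per_block trials per block (default 72)
#' @param set_size array size (default 4)
#' @param pre_blocks,adapt_blocks,post_blocks block-phase partition
#' @return an object of class `experiment_design`
#' @export
experiment_design <- function(n_blocks = 8L, trials_per_block = 72L,
                              set_size = 4L, pre_blocks = 1L,
                              adapt_blocks = 2:7, post_blocks = 8L) {
  stopifnot(
    n_blocks >= 1, trials_per_block >= 1, set_size >= 1,
    all(c(pre_blocks, adapt_blocks, post_blocks) %in% seq_len(n_blocks))
  )
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      set_size = as.integer(set_size),
      pre_blocks = as.integer(pre_blocks),
      adapt_blocks = as.integer(adapt_blocks),
      post_blocks = as.integer(post_blocks)
    ),
    class = "experiment_design"
  )
}

# empty trial table with the shared column layout; nontargets is a list
# column of radian vectors
empty_trial_table <- function() {
  data.frame(
    subject = character(0), condition = character(0), block = integer(0),
    set_size = integer(0), target = numeric(0),
    nontargets = I(list()), response = numeric(0)
  )
}

#' Generate a synthetic observer
#'
#' Simulates a continuous-report dataset in the layout of the fitted
#' studies: uniformly sampled targets at each requested set size, with
#' responses drawn from a generative model (neural resource or
#' slots-plus-averaging). Nontargets are sampled uniformly.
#'
#' @param model a `wm_popconfig` or an `spa_params`
#' @param set_sizes vector of set sizes (e.g. `c(1, 2, 4, 8)`)
#' @param trials_per_size trials per set size
#' @param seed optional integer seed
#' @param subject subject label (default "S1")
#' @param target_values optional vector of discrete target orientations
#'   (mapped radians). When supplied, targets are drawn as balanced,
#'   shuffled repetitions of these values instead of continuously
#'   uniform draws -- the design of studies with a fixed stimulus set,
#'   and the well-posed design for parameter-recovery tests of the
#'   binned likelihood (targets coincide with stimulus bin centers, so
#'   no within-bin jitter is misattributed to memory noise)
#' @return a trial table data.frame: `subject`, `condition`, `block`,
#'   `set_size`, `target`, `nontargets` (list column, radians),
#'   `response`
#' @export
gen_observer <- function(model, set_sizes, trials_per_size, seed = NULL,
                         subject = "S1", target_values = NULL) {
  stopifnot(trials_per_size >= 1, all(set_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(set_sizes, function(N) {
    tg <- if (is.null(target_values)) {
      stats::runif(trials_per_size, -pi, pi)
    } else {
      sample(rep_len(wrap_angle(target_values), trials_per_size))
    }
    resp <- if (inherits(model, "wm_popconfig")) {
      simulate_responses(model, tg, N)
    } else if (inherits(model, "spa_params")) {
      spa_sample(model, tg, N)$response
    } else {
      stop("gen_observer: model must be wm_popconfig or spa_params")
    }
    nt <- lapply(seq_len(trials_per_size), function(i) {
      if (N > 1) stats::runif(N - 1L, -pi, pi) else numeric(0)
    })
    data.frame(
      subject = subject, condition = "none", block = NA_integer_,
      set_size = as.integer(N), target = wrap_angle(tg),
      nontargets = I(nt), response = wrap_angle(resp)
    )
  })
  do.call(rbind, parts)
}

#' Generate a full adaptation experiment for one subject
#'
#' Targets are uniform in every block. Nontargets are uniform in the
#' pre and post blocks and are drawn from the manipulated bimodal
#' distribution during adaptation blocks: `adapt_oblique`
#' (\eqn{\propto 2 - |\cos\theta|}, peaks at the obliques) for the
#' incongruent condition, `adapt_cardinal`
#' (\eqn{\propto 2 - |\sin\theta|}, peaks at the cardinals, matching
#' natural scenes) for the congruent condition.
#'
#' Responses come from one of two backends:
#' * a per-block schedule of [mixture_params()] (phenomenological; fast,
#'   used for recovery tests): errors are von Mises around
#'   \eqn{\eta_b \sin(2\theta)} with probability \eqn{\lambda_b},
#'   uniform otherwise;
#' * a per-block schedule of [population_config()] objects
#'   (mechanistic), e.g. with priors interpolating between the natural
#'   prior and the adaptation distribution.
#'
#' @param design an [experiment_design()]
#' @param condition `"incongruent"` or `"congruent"`
#' @param schedule a list of length `design$n_blocks` whose elements
#'   are all `mixture_params` or all `wm_popconfig`
#' @param seed optional integer seed
#' @param subject subject label
#' @return a trial table data.frame (see [gen_observer()])
#' @export
gen_adaptation_experiment <- function(design, condition = c("incongruent", "congruent"),
                                      schedule, seed = NULL, subject = "S1") {
  stopifnot(inherits(design, "experiment_design"))
  condition <- match.arg(condition)
  if (length(schedule) != design$n_blocks) {
    stop("gen_adaptation_experiment: schedule must have one element per block")
  }
  if (!is.null(seed)) set.seed(seed)
  adapt_prior <- make_prior(
    if (condition == "incongruent") "adapt_oblique" else "adapt_cardinal"
  )
  N <- design$set_size
  parts <- lapply(seq_len(design$n_blocks), function(b) {
    nt_per <- design$trials_per_block
    tg <- stats::runif(nt_per, -pi, pi)
    nt <- if (b %in% design$adapt_blocks && N > 1) {
      draws <- prior_sample(adapt_prior, nt_per * (N - 1L))
      split(draws, rep(seq_len(nt_per), each = N - 1L))
    } else {
      lapply(seq_len(nt_per), function(i) {
        if (N > 1) stats::runif(N - 1L, -pi, pi) else numeric(0)
      })
    }
    mod <- schedule[[b]]
    resp <- if (inherits(mod, "mixture_params")) {
      mem <- stats::runif(nt_per) < mod$lambda
      r <- rvonmises(nt_per, wrap_angle(tg + mod$eta * sin(2 * tg)), mod$kappa)
      r[!mem] <- stats::runif(sum(!mem), -pi, pi)
      r
    } else if (inherits(mod, "wm_popconfig")) {
      simulate_responses(mod, tg, N)
    } else {
      stop("gen_adaptation_experiment: schedule elements must be mixture_params or wm_popconfig")
    }
    data.frame(
      subject = subject, condition = condition, block = b,
      set_size = N, target = wrap_angle(tg),
      nontargets = I(unname(nt)), response = wrap_angle(resp)
    )
  })
  do.call(rbind, parts)
}

#' Per-block prior schedule for the mechanistic adaptation backend
#'
#' Builds a list of priors that linearly interpolate (in density)
#' between the natural cardinal prior and the adaptation distribution,
#' one per block: weight 0 in the pre block, the supplied weights over
#' the adaptation blocks, and the final adaptation weight in the post
#' block (adaptation persists). The interpolation schedule is a free
#' modelling knob: no dynamic model of prior adaptation is implied.
#'
#' @param design an [experiment_design()]
#' @param condition `"incongruent"` or `"congruent"`
#' @param weights interpolation weights for the adaptation blocks,
#'   length `length(design$adapt_blocks)`, in \eqn{[0, 1]}
#' @return list of `wm_prior` objects, one per block
#' @export
adaptation_prior_schedule <- function(design, condition = c("incongruent", "congruent"),
                                      weights = seq(0.15, 0.9, length.out = 6)) {
  condition <- match.arg(condition)
  stopifnot(length(weights) == length(design$adapt_blocks), all(weights >= 0 & weights <= 1))
  nat <- make_prior("natural_cardinal")
  adapt <- make_prior(
    if (condition == "incongruent") "adapt_oblique" else "adapt_cardinal"
  )
  mix_prior <- function(w) {
    if (w == 0) return(nat)
    make_prior("custom", density = function(th) {
      (1 - w) * prior_density(nat, th) + w * prior_density(adapt, th)
    })
  }
  w_by_block <- numeric(design$n_blocks)
  w_by_block[design$adapt_blocks] <- weights
  w_by_block[design$post_blocks] <- weights[length(weights)]
  lapply(w_by_block, mix_prior)
}
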