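# Phase-space deconvolution and joint ADMM estimation of emission
# fluorescence and scattering potential.
#
# The emission update is a Richardson-Lucy-type multiplicative scheme cycled
# over angular components (center-out), which preserves non-negativity and
# converges quickly because each angular component is a well-conditioned 2D
# problem.  Scattered photons enter the forward model as an additive,
# PSF-imaged background recomputed from the current (I, F) at every outer
# iteration; F itself is updated by projected gradient descent with
# backtracking.  The two unknowns are coupled in a scaled-form ADMM loop
# with non-negativity consensus; the monitored data misfit must not
# increase across accepted outer iterations.

#' Reconstruction options
#'
#' @param outer_iterations ADMM outer iterations (emission + potential + dual).
#' @param inner_rl_iterations Richardson-Lucy cycles per emission update.
#' @param rho ADMM penalty parameter.
#' @param lambda_f Tikhonov weight for the scattering potential.
#' @param epsilon Division guard; default `1e-8 * max(views)`.
#' @param seed Integer seed for any stochastic choice (recorded in results).
#' @param convergence_tol Relative change of the emission estimate below
#'   which the outer loop stops early.
#' @return A list of options.
#' @export
recon_options <- function(outer_iterations = 3L, inner_rl_iterations = 10L,
                          rho = 1.0, lambda_f = 1e-3, epsilon = NULL,
                          seed = 1L, convergence_tol = 1e-4) {
  stopifnot(outer_iterations >= 1L, inner_rl_iterations >= 1L, rho > 0,
            lambda_f >= 0, convergence_tol > 0)
  list(outer_iterations = as.integer(outer_iterations),
       inner_rl_iterations = as.integer(inner_rl_iterations),
       rho = rho, lambda_f = lambda_f, epsilon = epsilon,
       seed = as.integer(seed), convergence_tol = convergence_tol)
}

# Center-out spiral ordering of angular components: the low-angle views
# carry most energy and stabilize the early multiplicative updates.
angular_order <- function(ppl) {
  half <- (ppl - 1L) %/% 2L
  g <- expand.grid(vi = seq_len(ppl), ui = seq_len(ppl))
  r2 <- (g$vi - half - 1L)^2 + (g$ui - half - 1L)^2
  ang <- atan2(g$vi - half - 1L, g$ui - half - 1L)
  g[order(r2, ang), c("vi", "ui")]
}

# Precompute per-angle RL normalizers backproject_u(1) for given projector
# and scan shifts; returns list keyed by angle index with one qlfm_volume.
rl_normalizers <- function(proj, grid, shifts = 0) {
  ppl <- proj$ppl
  ones <- matrix(1, grid$num_lenses[1], grid$num_lenses[2])
  ord <- angular_order(ppl)
  norms <- vector("list", nrow(ord))
  for (a in seq_len(nrow(ord))) {
    acc <- new_volume(grid, 0)
    for (sh in shifts) {
      acc <- back_angle(ones, acc, proj, ord$vi[a], ord$ui[a], sh)
    }
    norms[[a]] <- acc
  }
  norms
}

# One full RL cycle over all angular components.  views_list / backgrounds
# are lists over scan shifts; each angular focal stack (all shifts of one
# angle) is the unit whose error map drives one multiplicative update.
# `alpha` damps the multiplicative factor (factor^alpha); voxels with
# negligible sensitivity for an angle (normalizer below a relative floor)
# are left unchanged by that angle.
rl_cycle <- function(I, views_list, bg_list, proj, shifts, ord, norms, eps,
                     alpha = 1) {
  grid <- I$grid
  for (a in seq_len(nrow(ord))) {
    vi <- ord$vi[a]; ui <- ord$ui[a]
    bp <- new_volume(grid, 0)
    for (k in seq_along(shifts)) {
      fw <- forward_angle(I, proj, vi, ui, shifts[k])
      if (!is.null(bg_list)) fw <- fw + bg_list[[k]][vi, ui, , ]
      ratio <- views_list[[k]][vi, ui, , ] / (fw + eps)
      bp <- back_angle(ratio, bp, proj, vi, ui, shifts[k])
    }
    nrm <- norms[[a]]
    nfloor <- 1e-8 * max(vapply(nrm$slabs, max, numeric(1)))
    I$slabs <- Map(function(x, b, n) {
      r <- b / pmax(n, nfloor)
      r[n <= nfloor] <- 1
      r[r < 0] <- 0
      if (alpha != 1) r <- r^alpha
      x * r
    }, I$slabs, bp$slabs, nrm$slabs)
  }
  I
}

# Poisson negative log-likelihood of the views under the current model
# (up to the data-dependent constant).
poisson_nll <- function(I, views_list, bg_list, proj, psf, shifts, eps) {
  nll <- 0
  for (k in seq_along(shifts)) {
    fw <- forward_project(I, psf, proj, shifts[k])
    if (!is.null(bg_list)) fw <- fw + bg_list[[k]]
    f <- pmax(unclass(fw), eps)
    y <- unclass(views_list[[k]])
    nll <- nll + sum(f - y * log(f))
  }
  nll
}

# Simultaneous (all-angle) RL cycle: classic Richardson-Lucy with the
# angular components pooled into one error map.  Monotone for Poisson data,
# used as the fallback when sequential per-angle cycling oscillates.
rl_cycle_global <- function(I, views_list, bg_list, proj, shifts, ord,
                            norms, eps) {
  grid <- I$grid
  bp <- new_volume(grid, 0)
  for (a in seq_len(nrow(ord))) {
    vi <- ord$vi[a]; ui <- ord$ui[a]
    for (k in seq_along(shifts)) {
      fw <- forward_angle(I, proj, vi, ui, shifts[k])
      if (!is.null(bg_list)) fw <- fw + bg_list[[k]][vi, ui, , ]
      ratio <- views_list[[k]][vi, ui, , ] / (fw + eps)
      bp <- back_angle(ratio, bp, proj, vi, ui, shifts[k])
    }
  }
  ntot <- norms[[1]]
  for (a in 2:nrow(ord)) ntot <- volume_op(ntot, norms[[a]], `+`)
  nfloor <- 1e-8 * max(vapply(ntot$slabs, max, numeric(1)))
  I$slabs <- Map(function(x, b, n) {
    r <- b / pmax(n, nfloor)
    r[n <= nfloor] <- 1
    r[r < 0] <- 0
    x * r
  }, I$slabs, bp$slabs, ntot$slabs)
  I
}

# Run `n_cycles` RL cycles with monotone Poisson-loss enforcement.  Each
# iteration first tries the sequential per-angle cycle (fast convergence on
# well-modeled data); if that raises the loss the iteration is redone with
# the simultaneous all-angle update, which is monotone, and the run stays in
# simultaneous mode.  An iteration that still raises the loss ends the run.
run_rl <- function(I, views_list, bg_list, proj, psf, shifts, ord, norms,
                   eps, n_cycles, alpha = 1, mode = "sequential") {
  nll <- poisson_nll(I, views_list, bg_list, proj, psf, shifts, eps)
  trace <- nll
  for (it in seq_len(n_cycles)) {
    accepted <- FALSE
    for (try_k in 1:2) {
      I_new <- if (mode == "sequential") {
        rl_cycle(I, views_list, bg_list, proj, shifts, ord, norms, eps, alpha)
      } else {
        rl_cycle_global(I, views_list, bg_list, proj, shifts, ord, norms, eps)
      }
      nll_new <- poisson_nll(I_new, views_list, bg_list, proj, psf, shifts,
                             eps)
      if (nll_new <= nll + abs(nll) * 1e-12) {
        I <- I_new
        nll <- nll_new
        trace <- c(trace, nll)
        accepted <- TRUE
        break
      }
      if (mode == "global") break
      mode <- "global"
    }
    if (!accepted) break
  }
  list(I = I, nll_trace = trace, alpha = alpha, mode = mode)
}

#' Phase-space Richardson-Lucy deconvolution
#'
#' Multiplicative deconvolution of phase-space views onto a multiscale
#' volume, cycling over angular components, with no scattering model
#' (`F = 0`).  Non-negativity is preserved by construction; the Poisson data
#' loss is monitored over full cycles and the iteration stops (returning the
#' previous iterate) if it ever increases.
#'
#' @param views A `qlfm_views` array (non-negative).
#' @param psf A `qlfm_psf` covering the grid's planes.
#' @param grid A `qlfm_grid`.
#' @param opts Options from [recon_options()].
#' @param proj Optional precomputed projector.
#' @return A `qlfm_volume` with attributes `nll_trace` (Poisson loss per
#'   cycle) and `cycles`.
#' @export
phase_space_deconvolve <- function(views, psf, grid, opts = recon_options(),
                                   proj = NULL) {
  if (any(views < 0)) stop("views must be non-negative", call. = FALSE)
  if (all(views == 0)) {
    warning("all-zero views: returning zero volume", call. = FALSE)
    return(new_volume(grid, 0))
  }
  if (is.null(proj)) proj <- build_projector(psf, grid, shifts = 0)
  eps <- if (is.null(opts$epsilon)) 1e-8 * max(views) else opts$epsilon
  ord <- angular_order(proj$ppl)
  norms <- rl_normalizers(proj, grid)
  # back-projection start: mass placed where the data have support, scaled
  # so the initial forward projection matches total counts
  I <- backproject(views, psf, grid, proj)
  I <- volume_map(I, function(x) pmax(x, 0))
  f0 <- sum(forward_project(I, psf, proj))
  if (f0 <= 0) {
    I <- new_volume(grid, 1)
    f0 <- sum(forward_project(I, psf, proj))
  }
  I <- volume_map(I, function(x) x * sum(views) / max(f0, eps))
  vl <- list(views)
  res <- run_rl(I, vl, NULL, proj, psf, 0, ord, norms, eps,
                opts$inner_rl_iterations)
  I <- res$I
  attr(I, "nll_trace") <- res$nll_trace
  attr(I, "cycles") <- length(res$nll_trace) - 1L
  attr(I, "rl_damping") <- res$alpha
  I
}

#' Joint ADMM reconstruction of emission and scattering potential
#'
#' Alternates (a) Richardson-Lucy emission updates against the views with
#' the scattered contribution of the current `(I, F)` included as an
#' additive PSF-imaged background, (b) a projected-gradient update of the
#' scattering potential, and (c) scaled-dual non-negativity consensus steps
#' with penalty `rho`.  The squared-residual data misfit is monitored; an
#' outer iterate that increases it is rejected (the previous iterate is
#' kept), and three consecutive rejected/divergent iterations abort with
#' diagnostics.
#'
#' @param views A `qlfm_views` array.
#' @param psf A `qlfm_psf`.
#' @param grid A `qlfm_grid`.
#' @param opts Options from [recon_options()].
#' @param proj Optional precomputed projector.
#' @return List: `emission` and `potential` (`qlfm_volume`s), `misfit_trace`
#'   (accepted data misfit per outer iteration), `iterations`.
#' @export
admm_reconstruct <- function(views, psf, grid, opts = recon_options(),
                             proj = NULL) {
  if (is.null(proj)) proj <- build_projector(psf, grid, shifts = 0)
  config <- psf$config
  eps <- if (is.null(opts$epsilon)) 1e-8 * max(views) else opts$epsilon
  ord <- angular_order(proj$ppl)
  norms <- rl_normalizers(proj, grid)

  I <- phase_space_deconvolve(views, psf, grid, opts, proj)
  rl_alpha <- attr(I, "rl_damping")
  if (is.null(rl_alpha)) rl_alpha <- 1
  F_est <- new_volume(grid, 0)
  U_I <- new_volume(grid, 0)  # scaled duals of the non-negativity consensus
  U_F <- new_volume(grid, 0)

  data_misfit <- function(I, F_est) {
    S <- scattered_intensity(I, F_est, config)
    r <- forward_project(volume_op(I, S, `+`), psf, proj) - views
    sum(r^2)
  }
  misfit <- data_misfit(I, F_est)
  trace <- misfit
  diverged <- 0L
  for (it in seq_len(opts$outer_iterations)) {
    I_prev <- I; F_prev <- F_est
    # (a) emission update with the scattered background held fixed
    S <- scattered_intensity(I, F_est, config)
    bg <- forward_project(S, psf, proj)
    vl <- list(views)
    bgl <- list(bg)
    I <- run_rl(I, vl, bgl, proj, psf, 0, ord, norms, eps,
                opts$inner_rl_iterations, alpha = rl_alpha)$I
    # consensus: non-negativity projection with scaled dual
    Z_I <- volume_map(volume_op(I, U_I, `+`), function(x) pmax(x, 0))
    U_I <- volume_op(volume_op(U_I, I, `+`), Z_I, `-`)
    I <- Z_I
    # (b) potential update (projected gradient, backtracking)
    up <- update_potential(I, views, psf, F_est, lambda_f = opts$lambda_f,
                           proj = proj, config = config)
    F_est <- up$potential
    Z_F <- volume_map(volume_op(F_est, U_F, `+`), function(x) pmax(x, 0))
    U_F <- volume_op(volume_op(U_F, F_est, `+`), Z_F, `-`)
    F_est <- Z_F

    m_new <- data_misfit(I, F_est)
    if (m_new <= misfit * (1 + 1e-9)) {
      misfit <- m_new
      trace <- c(trace, m_new)
      diverged <- 0L
    } else {
      # reject the iterate: keep the previous one
      I <- I_prev; F_est <- F_prev
      trace <- c(trace, misfit)
      diverged <- diverged + 1L
      if (diverged >= 3L) {
        stop(sprintf(paste0("ADMM diverged: data misfit increased for 3 ",
                            "consecutive outer iterations (last accepted ",
                            "%.6g, proposed %.6g)"), misfit, m_new),
             call. = FALSE)
      }
    }
    rel <- volume_rel_change(I, I_prev)
    if (rel < opts$convergence_tol) break
  }
  list(emission = I, potential = F_est, misfit_trace = trace,
       iterations = length(trace) - 1L)
}

volume_rel_change <- function(a, b) {
  num <- sqrt(sum(vapply(seq_along(a$slabs),
                         function(i) sum((a$slabs[[i]] - b$slabs[[i]])^2),
                         numeric(1))))
  den <- sqrt(sum(vapply(b$slabs, function(x) sum(x^2), numeric(1))))
  if (den == 0) return(Inf)
  num / den
}

#' Joint reconstruction of an axially scanned acquisition
#'
#' Treats the scanned acquisition as one inverse problem on a single global
#' multiscale grid spanning all scan positions (plus out-of-focus margins):
#' the forward model for scan position `s` uses the PSF with depths shifted
#' by `s`, and each angular focal stack (one angular component across all
#' scan positions) is the unit over which the RL error map is computed.  No
#' per-position sub-volumes are reconstructed or stitched.
#'
#' @param frames List of `qlfm_views`, one per scan position.
#' @param scan_positions Strictly increasing axial scan positions (um).
#' @param config A `qlfm_config`.
#' @param model A `qlfm_resolution_model`.
#' @param opts Options from [recon_options()].
#' @param grid Optional `qlfm_grid`; built from the model when omitted.
#' @param psf Optional `qlfm_psf` with matching shifts; computed when omitted.
#' @param with_scattering Update the scattering potential as well (default
#'   TRUE).
#' @param coarse_margin Out-of-focus margin (um) beyond the scanned range
#'   covered by coarse slabs.
#' @param psf_opts Options for [psf_options()] when the PSF is computed here.
#' @return List as for [admm_reconstruct()] plus `grid` and `scan_positions`.
#' @export
reconstruct_axial_scan <- function(frames, scan_positions, config, model,
                                   opts = recon_options(), grid = NULL,
                                   psf = NULL, with_scattering = TRUE,
                                   coarse_margin = 120,
                                   psf_opts = psf_options()) {
  ns <- length(scan_positions)
  if (length(frames) != ns) stop("one frame per scan position required",
                                 call. = FALSE)
  if (is.unsorted(scan_positions, strictly = TRUE)) {
    stop("scan positions must be strictly increasing and distinct",
         call. = FALSE)
  }
  h <- model$high_res_half_range
  if (ns > 1L) {
    step <- min(diff(scan_positions))
    if (is.finite(h) && step > 2.5 * h) {
      warning("scan step exceeds the high-resolution axial range; coverage ",
              "between planes will be low-resolution", call. = FALSE)
    }
  }
  if (is.null(grid)) {
    half <- max(abs(scan_positions)) + min(h, 60)
    grid <- build_grid(-half - coarse_margin, half + coarse_margin, model,
                       config, fine_half_range = half)
  }
  if (is.null(psf)) {
    psf <- psf_for_grid(config, grid, opts = psf_opts,
                        scan_shifts = scan_positions)
  }
  if (ns == 1L && abs(scan_positions[1]) < 1e-9) {
    # degenerate case: a single unshifted frame is exactly the snapshot
    # reconstruction problem
    res <- admm_reconstruct(frames[[1]], psf, grid, opts)
    res$grid <- grid
    res$scan_positions <- scan_positions
    return(res)
  }
  proj <- build_projector(psf, grid, shifts = scan_positions)
  eps <- if (is.null(opts$epsilon)) 1e-8 * max(vapply(frames, max, numeric(1)))
         else opts$epsilon
  ord <- angular_order(proj$ppl)
  norms <- rl_normalizers(proj, grid, shifts = scan_positions)

  # initial flat volume scaled to the mean frame's counts
  I <- new_volume(grid, 1)
  f0 <- sum(forward_project(I, psf, proj, scan_positions[1]))
  I <- volume_map(I, function(x) x * mean(vapply(frames, sum, numeric(1))) /
                    max(f0, eps))
  F_est <- new_volume(grid, 0)
  misfit_scan <- function(I, F_est) {
    S <- scattered_intensity(I, F_est, config)
    tot <- volume_op(I, S, `+`)
    sum(vapply(seq_len(ns), function(k) {
      sum((forward_project(tot, psf, proj, scan_positions[k]) - frames[[k]])^2)
    }, numeric(1)))
  }
  misfit <- misfit_scan(I, F_est)
  trace <- misfit
  scan_alpha <- 1
  for (it in seq_len(opts$outer_iterations)) {
    I_prev <- I
    bgl <- NULL
    if (with_scattering) {
      S <- scattered_intensity(I, F_est, config)
      bgl <- lapply(scan_positions, function(sh) {
        forward_project(S, psf, proj, sh)
      })
    }
    rr <- run_rl(I, frames, bgl, proj, psf, scan_positions, ord, norms, eps,
                 opts$inner_rl_iterations, alpha = scan_alpha)
    I <- rr$I
    scan_alpha <- rr$alpha
    if (with_scattering) {
      # gradient step on F against the first frame's residual scale; all
      # frames share one volume so use the summed-residual gradient via the
      # unshifted projector path of update_potential on the mean frame
      k0 <- which.min(abs(scan_positions))
      up <- update_potential(I, frames[[k0]], psf, F_est,
                             lambda_f = opts$lambda_f, config = config,
                             proj = proj, shift = scan_positions[k0])
      F_est <- up$potential
    }
    m_new <- misfit_scan(I, F_est)
    if (m_new <= misfit * (1 + 1e-9)) {
      misfit <- m_new
      trace <- c(trace, m_new)
    } else {
      I <- I_prev
      trace <- c(trace, misfit)
    }
    if (volume_rel_change(I, I_prev) < opts$convergence_tol) break
  }
  list(emission = I, potential = F_est, misfit_trace = trace,
       iterations = length(trace) - 1L, grid = grid,
       scan_positions = scan_positions)
}
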