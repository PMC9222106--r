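# Synthetic paired-hemisphere LFP with full ground truth.
#
# Signal model per channel:
#   LFP = state wave (logistic up/down transitions, swing `delta$amp`)
#       + 1/f^chi background + white noise floor
#       + gamma-band noise gated to up states
#       + extracellular unit waveforms at state-dependent Poisson rates
#       + (mosaic injected channel) beta bursts and hypersynchronous
#         event templates coupled to the contralateral up-state set.
#
# A hypersynchronous discharge locally interrupts the ongoing slow
# oscillation (the network fires en masse, then is suppressed), so by
# default the state-wave and gamma components are cross-faded out around
# each injected event before the template is added.

# --- state sequence ---------------------------------------------------------

gen_dwell <- function(n, shape, mean) {
  if (is.infinite(shape)) rep(mean, n) else rgamma(n, shape = shape, scale = mean / shape)
}

gen_states <- function(state, duration) {
  cycle <- state$us_mean + state$ds_mean
  n_guess <- ceiling(duration / cycle * 1.5) + 20L
  repeat {
    ds <- gen_dwell(n_guess, state$ds_shape, state$ds_mean)
    us <- gen_dwell(n_guess, state$us_shape, state$us_mean)
    bounds <- cumsum(as.vector(rbind(ds, us)))
    if (bounds[length(bounds)] > duration) break
    n_guess <- n_guess * 2L
  }
  on <- bounds[seq(1L, length(bounds), by = 2L)]   # DS -> US
  off <- bounds[seq(2L, length(bounds), by = 2L)]  # US -> DS
  keep <- on < duration
  on <- on[keep]; off <- pmin(off[keep], duration)
  us_iv <- interval_set(on, off, label = "US")
  list(us = us_iv, ds = iv_complement(us_iv, 0, duration, label = "DS"))
}

#' Generate an alternating up/down state sequence
#'
#' Dwell times are drawn from per-state gamma distributions
#' (`shape = Inf` gives a strictly periodic sequence). Deterministic under
#' the configuration seed; [generate_lfp_pair()] with the same config uses
#' the identical sequence.
#'
#' @param cfg a [synth_config()].
#' @return list with `us` and `ds` [interval_set()]s covering
#'   `[0, cfg$duration)`.
#' @export
generate_state_sequence <- function(cfg) {
  validate_synth_config(cfg)
  with_seed(cfg$seed, gen_states(cfg$state, cfg$duration))
}

# --- waveform building blocks ----------------------------------------------

# square state wave +/- amp/2 with logistic transitions of time-constant tau
state_wave <- function(us, duration, fs, amp, tau, lag = 0) {
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  w <- ifelse(iv_contains(tt - lag, us), amp / 2, -amp / 2)
  # replace each step by a logistic ramp: add the (local) correction term
  tb_all <- c(us$start + lag, us$end + lag)
  sgn_all <- rep(c(1, -1), c(nrow(us), nrow(us)))
  half <- as.integer(ceiling(10 * tau * fs))
  for (k in seq_along(tb_all)) {
    tb <- tb_all[k]
    i0 <- max(1L, as.integer(floor(tb * fs)) + 1L - half)
    i1 <- min(n, as.integer(ceiling(tb * fs)) + 1L + half)
    if (i0 > i1) next
    idx <- i0:i1
    ti <- tt[idx]
    w[idx] <- w[idx] + sgn_all[k] * amp *
      (stats::plogis((ti - tb) / tau) - (ti >= tb))
  }
  w
}

# 1/f^chi noise by spectral shaping of white noise, flattened below f_min
one_over_f_noise <- function(n, fs, chi, rms, f_min = 0.1) {
  if (rms <= 0) return(numeric(n))
  np <- stats::nextn(n, c(2, 3, 5))
  wht <- rnorm(np)
  k <- 0:(np - 1L)
  freq <- pmin(k, np - k) * fs / np
  shape <- pmax(freq, f_min)^(-chi / 2)
  shape[1L] <- 0
  y <- Re(stats::fft(stats::fft(wht) * shape, inverse = TRUE)) / np
  y <- y[seq_len(n)]
  y * rms / sqrt(mean(y^2))
}

# band-limited Gaussian noise with unit RMS; steep edges so the synthesized
# content actually honors the declared band
band_noise <- function(n, fs, f_lo, f_hi, ord = 30L) {
  y <- fft_filter(rnorm(n), fs,
                  function(f) sqrt(butter_fb_response(f, f_lo, f_hi, ord)))
  y / sqrt(mean(y^2))
}

# difference-of-exponentials event template; returns samples, peak index,
# and the 25%-of-peak boundary offsets (seconds, relative to template start)
hypersync_template <- function(fs, amp, width25 = 0.23, tau_r = 0.02) {
  width_at_25 <- function(tau_d) {
    tp <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
    h <- function(t) (exp(-t / tau_d) - exp(-t / tau_r))
    pk <- h(tp)
    lev <- 0.25 * pk
    t1 <- stats::uniroot(function(t) h(t) - lev, c(1e-6, tp))$root
    t2 <- stats::uniroot(function(t) h(t) - lev, c(tp, 60 * tau_d))$root
    t2 - t1
  }
  tau_d <- stats::uniroot(function(td) width_at_25(td) - width25,
                          c(tau_r * 1.2, 5))$root
  tp <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
  t_end <- -tau_d * log(0.005)
  tt <- seq(0, t_end, by = 1 / fs)
  h <- exp(-tt / tau_d) - exp(-tt / tau_r)
  h <- h / max(h) * amp
  pk_val <- max(h)
  lev <- 0.25
  hn <- h / pk_val
  i_pk <- which.max(hn)
  i1 <- which(hn >= lev)[1L]
  i2 <- i_pk + which(hn[i_pk:length(hn)] < lev)[1L] - 2L
  list(samples = h, peak_idx = i_pk, fs = fs,
       b_lo = (i1 - 1L) / fs, b_hi = (i2 - 1L) / fs, tau_d = tau_d)
}

# place events: with probability p inside the coupled interval set, else
# uniformly in its complement; p = NA places uniformly over the window
place_event_times <- function(n_ev, iv, duration, p, margin = 1) {
  if (n_ev == 0L) return(list(times = numeric(0), coupled = logical(0)))
  win <- c(margin, duration - margin)
  iv_in <- iv_intersect(iv, interval_set(win[1], win[2]))
  iv_out <- iv_complement(iv, win[1], win[2])
  draw_in <- function(k, set) {
    if (!nrow(set) || k == 0L) return(runif(k, win[1], win[2]))
    len <- set$end - set$start
    pick <- sample.int(nrow(set), k, replace = TRUE, prob = len)
    set$start[pick] + runif(k) * len[pick]
  }
  if (is.na(p)) {
    times <- runif(n_ev, win[1], win[2])
    coupled <- rep(NA, n_ev)
  } else {
    coupled <- runif(n_ev) < p
    times <- numeric(n_ev)
    times[coupled] <- draw_in(sum(coupled), iv_in)
    times[!coupled] <- draw_in(sum(!coupled), iv_out)
  }
  o <- order(times)
  list(times = times[o], coupled = coupled[o])
}

# add short kernels at many spike times via offset accumulation
add_kernels <- function(y, idx, kernel, center) {
  n <- length(y)
  for (j in seq_along(kernel)) {
    pos <- idx + (j - center)
    ok <- pos >= 1L & pos <= n
    if (any(ok)) y <- y + kernel[j] * tabulate(pos[ok], nbins = n)
  }
  y
}

unit_kernel <- function(fs, width_ms, amp) {
  sig <- width_ms / 1000 / 4
  tt <- seq(-3 * sig, 6 * sig, by = 1 / fs)
  w <- -exp(-(tt / sig)^2 / 2) + 0.35 * exp(-((tt - 2.5 * sig) / (1.8 * sig))^2 / 2)
  w <- w / max(abs(w)) * amp
  list(samples = w, center = which.min(w))
}

draw_state_spikes <- function(us, ds, duration, rate_us, rate_ds, dead = 0.001) {
  spikes_in <- function(set, rate) {
    if (!nrow(set) || rate <= 0) return(numeric(0))
    len <- set$end - set$start
    counts <- rpois(nrow(set), rate * len)
    unlist(lapply(which(counts > 0L), function(k) {
      sort(set$start[k] + runif(counts[k]) * len[k])
    }))
  }
  t_all <- sort(c(spikes_in(us, rate_us), spikes_in(ds, rate_ds)))
  if (length(t_all) > 1L) {
    keep <- c(TRUE, diff(t_all) >= dead)
    t_all <- t_all[keep]
  }
  t_all
}

# --- paired-hemisphere LFP ---------------------------------------------------

#' Generate a paired-hemisphere LFP recording with ground truth
#'
#' Both hemispheres share one up/down state sequence; the injected channel
#' lags it by `cfg$lag_ms`. Under `profile = "mosaic"` the injected channel
#' additionally carries beta bursts and hypersynchronous events whose
#' placement is coupled to the contralateral (control-channel) up-state set:
#' each event lands inside a contralateral up state with probability `p_us`
#' and uniformly outside them otherwise (`p_us = NA` places events
#' uniformly regardless of state).
#'
#' @param cfg a [synth_config()]; `cfg$profile` selects the condition.
#' @param return_components if `TRUE`, noiseless component sums are stored
#'   in the ground truth (for oracle checks).
#' @return list with `recording` (channels `lfp_injected`, `lfp_control`)
#'   and `truth`, a `ground_truth` list holding `us` (control clock),
#'   `us_injected`, `bursts`, `spikes` (hypersynchronous events),
#'   `unit_times` per channel, and the realized event coupling flags.
#' @export
generate_lfp_pair <- function(cfg, return_components = FALSE) {
  validate_synth_config(cfg)
  fs <- cfg$fs_lfp
  dur <- cfg$duration
  n <- as.integer(round(dur * fs))
  lag <- cfg$lag_ms / 1000

  with_seed(cfg$seed, {
    states <- gen_states(cfg$state, dur)
    us <- states$us
    truth <- list(us = us, ds = states$ds,
                  us_injected = interval_set(pmin(us$start + lag, dur),
                                             pmin(us$end + lag, dur + 1e-9),
                                             label = "US"),
                  bursts = event_table(type = "beta_burst"),
                  spikes = event_table(type = "hypersync_spike"),
                  unit_times = list(), components = list())

    build_channel <- function(role) {
      p <- chan_params(cfg, role)
      this_lag <- if (role == "injected") lag else 0
      sw <- state_wave(us, dur, fs, p$delta_amp, p$tau_tr, lag = this_lag)
      ind <- (state_wave(us, dur, fs, 1, p$tau_tr, lag = this_lag) + 0.5)

      gm <- numeric(n)
      if (fs / 2 > 45 && cfg$gamma$rms > 0) {
        g_hi <- min(100, 0.45 * fs)
        gm <- band_noise(n, fs, 40, g_hi) * ind
        in_us_rms <- sqrt(mean(gm[ind > 0.5]^2))
        if (in_us_rms > 0) gm <- gm * cfg$gamma$rms / in_us_rms
      }

      uk <- NULL; ut <- numeric(0)
      spikes_sig <- numeric(n)
      if (fs >= 1000 && (p$rate_us > 0 || p$rate_ds > 0) && cfg$units$amp > 0) {
        us_l <- if (this_lag > 0) truth$us_injected else us
        ds_l <- iv_complement(us_l, 0, dur)
        ut <- draw_state_spikes(us_l, ds_l, dur, p$rate_us, p$rate_ds)
        uk <- unit_kernel(fs, cfg$units$width_ms, cfg$units$amp)
        idx <- pmin(n, pmax(1L, as.integer(round(ut * fs)) + 1L))
        spikes_sig <- add_kernels(spikes_sig, idx, uk$samples, uk$center)
      }

      bg <- one_over_f_noise(n, fs, p$chi, cfg$background$rms,
                             cfg$background$f_min) +
        rnorm(n) * cfg$background$white_rms
      if (cfg$background$gaba_rms > 0) {
        # inhibition surrogate: extra steep-spectrum power concentrated in
        # the exponent-fit band (flattened below 1 Hz, so its variance sits
        # between 1 and 50 Hz rather than in the sub-delta range)
        bg <- bg + one_over_f_noise(n, fs, cfg$background$gaba_chi,
                                    cfg$background$gaba_rms, f_min = 1)
      }

      list(sw = sw, gm = gm, spikes_sig = spikes_sig, bg = bg,
           unit_times = ut, params = p)
    }

    ch_inj <- build_channel("injected")
    ch_ctl <- build_channel("control")

    tt <- (seq_len(n) - 1) / fs
    p_inj <- ch_inj$params

    # beta bursts on the injected channel, coupled to contralateral USs
    burst_sig <- numeric(n)
    if (p_inj$burst_rate > 0) {
      n_b <- rpois(1L, p_inj$burst_rate * dur / 3600)
      pl <- place_event_times(n_b, us, dur, cfg$burst$p_us, margin = 2)
      if (n_b > 0L) {
        d_b <- rlnorm(n_b, cfg$burst$dur_meanlog, cfg$burst$dur_sdlog)
        ph <- runif(n_b, 0, 2 * pi)
        for (k in seq_len(n_b)) {
          i0 <- max(1L, as.integer(round((pl$times[k] - d_b[k] / 2) * fs)) + 1L)
          i1 <- min(n, as.integer(round((pl$times[k] + d_b[k] / 2) * fs)))
          if (i1 <= i0) next
          seg <- i0:i1
          env <- hann_window(length(seg))
          burst_sig[seg] <- burst_sig[seg] + cfg$burst$amp * env *
            sin(2 * pi * cfg$burst$carrier * tt[seg] + ph[k])
        }
        truth$bursts <- event_table(pl$times, pl$times - d_b / 2,
                                    pl$times + d_b / 2,
                                    amplitude = rep(cfg$burst$amp, n_b),
                                    channel = "lfp_injected",
                                    type = "beta_burst")
        truth$burst_coupled <- pl$coupled
      }
    }

    # hypersynchronous events on the injected channel
    hs_sig <- numeric(n)
    suppress <- rep(1, n)
    if (p_inj$hypersync_rate > 0) {
      tpl <- hypersync_template(fs, cfg$hypersync$amp, cfg$hypersync$width25,
                                cfg$hypersync$tau_r)
      n_h <- rpois(1L, p_inj$hypersync_rate * dur / 3600)
      pl <- place_event_times(n_h, us, dur, cfg$hypersync$p_us, margin = 2)
      if (n_h > 0L) {
        pk_off <- (tpl$peak_idx - 1L) / fs
        for (k in seq_len(n_h)) {
          i0 <- as.integer(round((pl$times[k] - pk_off) * fs)) + 1L
          i1 <- i0 + length(tpl$samples) - 1L
          j <- max(1L, i0):min(n, i1)
          hs_sig[j] <- hs_sig[j] + tpl$samples[j - i0 + 1L]
          if (cfg$hypersync$suppress_swa) {
            # raised-cosine cross-fade of the slow oscillation around the event
            s0 <- pl$times[k] - pk_off - 0.10
            s1 <- pl$times[k] + tpl$b_hi - pk_off + 0.25
            jj <- max(1L, as.integer(floor((s0 - 0.1) * fs)) + 1L):
                  min(n, as.integer(ceiling((s1 + 0.1) * fs)) + 1L)
            tj <- tt[jj]
            w <- rep(0, length(jj))
            w[tj < s0] <- 0.5 + 0.5 * cos(pi * pmax(0, pmin(1, (tj[tj < s0] - (s0 - 0.1)) / 0.1)))
            w[tj > s1] <- 0.5 - 0.5 * cos(pi * pmax(0, pmin(1, (tj[tj > s1] - s1) / 0.1)))
            suppress[jj] <- pmin(suppress[jj], w)
          }
        }
        truth$spikes <- event_table(
          pl$times, pl$times - (pk_off - tpl$b_lo), pl$times + (tpl$b_hi - pk_off),
          amplitude = rep(cfg$hypersync$amp, n_h),
          channel = "lfp_injected", type = "hypersync_spike")
        truth$spike_coupled <- pl$coupled
      }
    }

    inj_clean <- (ch_inj$sw + ch_inj$gm) * suppress + ch_inj$spikes_sig +
      burst_sig + hs_sig
    ctl_clean <- ch_ctl$sw + ch_ctl$gm + ch_ctl$spikes_sig
    inj <- inj_clean + ch_inj$bg
    ctl <- ctl_clean + ch_ctl$bg

    truth$unit_times <- list(lfp_injected = ch_inj$unit_times,
                             lfp_control = ch_ctl$unit_times)
    if (return_components) {
      truth$components <- list(injected_clean = inj_clean,
                               control_clean = ctl_clean)
    }
    class(truth) <- "ground_truth"

    rec <- recording(
      list(lfp_injected = time_series(inj, fs, label = "lfp_injected"),
           lfp_control = time_series(ctl, fs, label = "lfp_control")),
      animal_id = sprintf("sim%04d", cfg$seed),
      group = if (cfg$profile == "mosaic") "mosaic_pup" else "control",
      hemisphere_map = c(lfp_injected = "injected",
                         lfp_control = "control_hemisphere"))
    list(recording = rec, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d USs, %d bursts, %d hypersync events\n",
              nrow(x$us), nrow(x$bursts), nrow(x$spikes)))
  invisible(x)
}
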