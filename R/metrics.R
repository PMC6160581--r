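#' Flow-weighted statistics
#'
#' Population-convention weighted moments: the weighted SD uses
#' `sqrt(sum(w (x - mean_w)^2) / sum(w))` with no Bessel correction.
#'
#' @param x Values.
#' @param w Non-negative weights with positive sum.
#' @return Scalar statistic.
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (sum(w) <= 0) stop("weights sum to zero", call. = FALSE)
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(weighted_mean((x - m)^2, w))
}

#' @rdname weighted_mean
#' @export
weighted_cov <- function(x, w) {
  weighted_sd(x, w) / weighted_mean(x, w)
}

#' Enumerate inflow-to-outflow capillary paths
#'
#' Depth-first enumeration of all directed paths from functional inflow to
#' outflow vessels. Each path carries the probability that a randomly chosen
#' RBC takes it: the RBC-flux share of its inflow vessel times the RBC-flux
#' split fraction at every diverging bifurcation encountered, so the weights
#' sum to one. If more than `max_paths` paths exist the smallest-weight
#' paths are dropped and the weights renormalized (the truncated weight is
#' recorded in attribute `"truncated_weight"`).
#'
#' @param net A `capnet` with a solved flow + hematocrit state.
#' @param max_paths Path-count cap.
#' @return Tibble with columns `path_id`, `vessels` (list of vessel ids),
#'   `n_vessels`, `length` (um), `tau` (s), `weight`.
#' @export
enumerate_paths <- function(net, max_paths = 10000) {
  stop_if_no_flow(net)
  v <- net$vessels
  de <- directed_ends(net)
  speed <- abs(v$v_rbc)
  live <- which(!de$zero_flow & speed > 0)
  bnd_nodes <- net$nodes$node[net$nodes$boundary != "interior"]
  children <- vector("list", nrow(v))
  child_prob <- vector("list", nrow(v))
  for (i in live) {
    ch <- live[de$tail[live] == de$head[i]]
    children[[i]] <- ch
    if (length(ch) > 0) {
      pr <- v$q_rbc[ch]
      if (sum(pr) <= 0) pr <- rep(1, length(ch))
      child_prob[[i]] <- pr / sum(pr)
    }
  }
  roots <- live[de$tail[live] %in% bnd_nodes]
  if (length(roots) == 0) stop("no inflow vessels with flow", call. = FALSE)
  w_root <- v$q_rbc[roots]
  if (sum(w_root) <= 0) w_root <- rep(1, length(roots))
  w_root <- w_root / sum(w_root)
  res_path <- list(); res_w <- numeric(0)
  res_len <- numeric(0); res_tau <- numeric(0)
  lost_w <- 0
  # iterative DFS
  stack <- purrr::map2(roots, w_root, function(i, w)
    list(i = i, w = w, path = i, len = v$length[i],
         tau = v$length[i] / speed[i]))
  hard_cap <- 20L * max_paths
  while (length(stack) > 0) {
    it <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ch <- children[[it$i]]
    if (length(ch) == 0) {
      if (de$head[it$i] %in% bnd_nodes) {
        res_path[[length(res_path) + 1]] <- it$path
        res_w <- c(res_w, it$w)
        res_len <- c(res_len, it$len)
        res_tau <- c(res_tau, it$tau)
        if (length(res_w) > hard_cap) break
      } else {
        lost_w <- lost_w + it$w   # dead interior end (zero-flow pocket)
      }
      next
    }
    pr <- child_prob[[it$i]]
    for (k in seq_along(ch)) {
      wk <- it$w * pr[k]
      j <- ch[k]
      stack[[length(stack) + 1]] <- list(
        i = j, w = wk, path = c(it$path, j),
        len = it$len + v$length[j], tau = it$tau + v$length[j] / speed[j])
    }
  }
  truncated <- 0
  if (length(res_w) > max_paths) {
    keep <- order(-res_w)[seq_len(max_paths)]
    truncated <- sum(res_w[-keep])
    res_path <- res_path[keep]; res_w <- res_w[keep]
    res_len <- res_len[keep]; res_tau <- res_tau[keep]
  }
  res_w <- res_w / sum(res_w)
  out <- tibble::tibble(
    path_id = seq_along(res_w),
    vessels = purrr::map(res_path, ~ v$vessel[.x]),
    n_vessels = lengths(res_path),
    length = res_len, tau = res_tau, weight = res_w
  )
  attr(out, "truncated_weight") <- truncated + lost_w
  out
}

#' Per-path outflow saturation from the transport equation
#'
#' Chains the single-vessel saturation map along every enumerated path,
#' using the extraction rates implied by the given tissue radii.
#'
#' @param net A solved `capnet`.
#' @param paths Tibble from [enumerate_paths()].
#' @param r_t Tibble (`vessel`, `r_t`) of tissue radii.
#' @param inflow_s Tibble (`vessel`, `s_a`).
#' @param params An [oxygen_params()] list.
#' @return `paths` with columns `s_a`, `s_v` and `delta_s` added.
#' @export
path_outflow_ode <- function(net, paths, r_t, inflow_s,
                             params = oxygen_params()) {
  v <- net$vessels
  jt <- extraction_rate(r_t$r_t[match(v$vessel, r_t$vessel)], v$r_w,
                        params$m0)
  if (anyNA(jt)) stop("r_t missing for some vessels", call. = FALSE)
  s_map <- inflow_s$s_a[match(v$vessel, inflow_s$vessel)]
  s_fallback <- mean(inflow_s$s_a)
  idx_of <- function(vid) match(vid, v$vessel)
  s_a <- numeric(nrow(paths)); s_v <- numeric(nrow(paths))
  if (params$alpha_eff == 0) {
    drop <- jt * v$length /
      (abs(v$v_rbc) * v$mu_ld * pi * v$r_c^2 * params$c0)
    for (p in seq_len(nrow(paths))) {
      idx <- idx_of(paths$vessels[[p]])
      s0 <- s_map[idx[1]]
      if (is.na(s0)) s0 <- s_fallback
      s_a[p] <- s0
      s_v[p] <- max(0, s0 - sum(drop[idx]))
    }
  } else {
    for (p in seq_len(nrow(paths))) {
      idx <- idx_of(paths$vessels[[p]])
      s0 <- s_map[idx[1]]
      if (is.na(s0)) s0 <- s_fallback
      s_a[p] <- s0
      s <- s0
      for (i in idx) {
        s <- vessel_forward(s, jt[i], abs(v$v_rbc[i]), v$mu_ld[i],
                            v$r_c[i], v$r_p[i], v$length[i], params)
      }
      s_v[p] <- s
    }
  }
  paths$s_a <- s_a
  paths$s_v <- s_v
  paths$delta_s <- s_a - s_v
  paths
}

#' Three-way COSH model comparison
#'
#' Compares the flow-weighted SD of distal saturation (COSH) across the
#' three model variants: the transport ODE with geometric tissue radii (no
#' diffusive interaction), the ODE with functional radii (capillary
#' interaction only) and the Lagrangian moving-RBC model (full interaction).
#' The total COSH reduction is split into the capillary share (geometric to
#' functional) and the RBC share (functional to Lagrangian).
#'
#' @param ode_geometric,ode_functional,lagrangian Outflow saturation sets:
#'   tibbles/data frames with columns `s` (or `s_v`/`s_out`) and optionally
#'   `w`.
#' @return An object of class `cosh_comparison`.
#' @export
compare_models <- function(ode_geometric, ode_functional, lagrangian) {
  get_sw <- function(x) {
    s <- if ("s" %in% names(x)) x$s else if ("s_v" %in% names(x)) x$s_v
    else x$s_out
    w <- if ("w" %in% names(x)) x$w
    else if ("weight" %in% names(x)) x$weight else rep(1, length(s))
    list(s = s, w = w)
  }
  sets <- list(ode_geometric = get_sw(ode_geometric),
               ode_functional = get_sw(ode_functional),
               lagrangian = get_sw(lagrangian))
  tab <- purrr::imap_dfr(sets, function(sw, nm) tibble::tibble(
    model = nm, n = length(sw$s),
    mean_s_v = weighted_mean(sw$s, sw$w),
    cosh = weighted_sd(sw$s, sw$w),
    frac_below_0.2 = weighted_mean(sw$s < 0.2, sw$w)
  ))
  cg <- tab$cosh[tab$model == "ode_geometric"]
  cf <- tab$cosh[tab$model == "ode_functional"]
  cl <- tab$cosh[tab$model == "lagrangian"]
  total <- (cg - cl) / cg * 100
  structure(list(
    table = tab,
    reduction_total = total,
    reduction_capillary = (cg - cf) / cg * 100,
    reduction_rbc = (cf - cl) / cg * 100,
    share_capillary = if (cg > cl) (cg - cf) / (cg - cl) * 100 else NA_real_,
    share_rbc = if (cg > cl) (cf - cl) / (cg - cl) * 100 else NA_real_
  ), class = "cosh_comparison")
}

#' @export
print.cosh_comparison <- function(x, ...) {
  cat("<cosh_comparison>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("  COSH reduction: %.1f%% total (capillary %.1f%%, RBC %.1f%%)\n",
              x$reduction_total, x$reduction_capillary, x$reduction_rbc))
  invisible(x)
}

#' Heterogeneity and correlation summary
#'
#' COSH/CTH statistics of a set of path records, plus the correlation pairs
#' relating saturation drops to transit times and path lengths and (when
#' territory data are given) the functional tissue radii to their geometric
#' counterparts, the vessel saturation and the RBC flow. Correlations are
#' Pearson with two-sided t-test p-values; the widths of the functional and
#' geometric radius distributions are compared with an F-test.
#'
#' @param paths Path records with `s_a`, `s_v`, `delta_s`, `tau`, `length`
#'   and `weight` columns (e.g. from [path_outflow_ode()], or built from
#'   Lagrangian exit records).
#' @param territories Optional tibble with `r_t_geo`, `r_t_fun` and
#'   optionally `s_mean`, `q_rbc` per vessel.
#' @return An object of class `heterogeneity_summary`.
#' @export
correlation_suite <- function(paths, territories = NULL) {
  stopifnot(nrow(paths) >= 3)
  w <- paths$weight
  cor_row <- function(a, b, label) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) < 1e-12 ||
        stats::sd(b[ok]) < 1e-12) {
      return(tibble::tibble(pair = label, n = sum(ok), r = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(a[ok], b[ok])
    tibble::tibble(pair = label, n = sum(ok), r = unname(ct$estimate),
                   p_value = ct$p.value, degenerate = FALSE)
  }
  cors <- dplyr::bind_rows(
    cor_row(paths$delta_s, paths$tau, "delta_s_vs_tau"),
    cor_row(paths$delta_s, paths$length, "delta_s_vs_length")
  )
  f_test <- NULL
  if (!is.null(territories)) {
    cors <- dplyr::bind_rows(
      cors,
      cor_row(territories$r_t_fun, territories$r_t_geo,
              "r_fun_vs_r_geo"),
      if ("s_mean" %in% names(territories)) {
        cor_row(territories$r_t_fun, territories$s_mean, "r_fun_vs_s_mean")
      },
      if ("q_rbc" %in% names(territories)) {
        cor_row(territories$r_t_fun, territories$q_rbc, "r_fun_vs_q_rbc")
      }
    )
    ok <- is.finite(territories$r_t_fun) & is.finite(territories$r_t_geo)
    if (sum(ok) >= 3) {
      vt <- stats::var.test(territories$r_t_fun[ok],
                            territories$r_t_geo[ok])
      f_test <- list(sd_fun = stats::sd(territories$r_t_fun[ok]),
                     sd_geo = stats::sd(territories$r_t_geo[ok]),
                     f = unname(vt$statistic), p_value = vt$p.value)
    }
  }
  structure(list(
    mean_s_v = weighted_mean(paths$s_v, w),
    cosh = weighted_sd(paths$s_v, w),
    mean_delta_s = weighted_mean(paths$delta_s, w),
    sd_delta_s = weighted_sd(paths$delta_s, w),
    cov_delta_s = weighted_cov(paths$delta_s, w),
    mean_tau = weighted_mean(paths$tau, w),
    cth = weighted_sd(paths$tau, w),
    cov_tau = weighted_cov(paths$tau, w),
    frac_below_0.2 = weighted_mean(paths$s_v < 0.2, w),
    correlations = cors,
    f_test_radii = f_test,
    n_paths = nrow(paths)
  ), class = "heterogeneity_summary")
}

#' @export
print.heterogeneity_summary <- function(x, ...) {
  cat("<heterogeneity_summary>\n")
  cat(sprintf("  S_v %.3f +/- %.4f (COSH), dS %.4f (CoV %.3f)\n",
              x$mean_s_v, x$cosh, x$mean_delta_s, x$cov_delta_s))
  cat(sprintf("  tau %.3f s +/- %.3f (CTH, CoV %.3f); frac S_v<0.2: %.3f\n",
              x$mean_tau, x$cth, x$cov_tau, x$frac_below_0.2))
  print(as.data.frame(x$correlations), row.names = FALSE)
  invisible(x)
}

#' Path records from Lagrangian exit events
#'
#' Converts the exit records of a [simulate_rbc_transport()] run (averaging
#' window only) into the path-record format used by [correlation_suite()]
#' (equal RBC weights: each exiting RBC is one sample of the RBC-flux
#' weighted path ensemble).
#'
#' @param run A `lagrangian_run`.
#' @return Tibble with `s_a`, `s_v`, `delta_s`, `tau`, `length`, `weight`.
#' @export
lagrangian_paths <- function(run) {
  w <- run$exits[run$exits$in_window, ]
  tibble::tibble(
    s_a = w$s_in, s_v = w$s_out, delta_s = w$s_in - w$s_out,
    tau = w$transit_time, length = w$path_length,
    weight = rep(1 / nrow(w), nrow(w))
  )
}
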