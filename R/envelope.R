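# Charge-state envelope assignment and relative quantification.

#' Assign isotopic envelopes to centroid peaks
#'
#' For each candidate proteoform and charge state, places the theoretical
#' aggregated isotope pattern on the m/z axis and matches its isotopologue
#' positions to observed centroids within `tol_ppm`. Matching is globally
#' greedy by absolute ppm error, and each centroid is consumed by at most
#' one envelope. Envelopes with fewer than `min_peaks` matched isotopologues
#' are discarded as noise matches.
#'
#' @param centroids A centroid `mass_spectrum`.
#' @param candidates List of `proteoform` objects, or a candidate table
#'   from [enumerate_candidates()] (its `proteoform` list-column is used).
#' @param charges Integer vector of charge states to try.
#' @param tol_ppm Peak matching tolerance, ppm (default 1).
#' @param min_peaks Minimum matched isotopologues per accepted envelope.
#' @param min_isotopologue_frac Theoretical isotopologues below this
#'   fraction of the pattern maximum are not searched for.
#' @return A list of envelopes; each is a list with fields `label`,
#'   `charge`, and `peaks` (data.frame: `offset`, `mz_theoretical`,
#'   `mz_observed`, `intensity`, `error_ppm`) plus `intensity`, the summed
#'   matched intensity.
#' @export
assign_envelopes <- function(centroids, candidates, charges, tol_ppm = 1,
                             min_peaks = 3, min_isotopologue_frac = 0.01) {
  stopifnot(inherits(centroids, "mass_spectrum"),
            centroids$mode == "centroid")
  if (is.data.frame(candidates)) candidates <- candidates$proteoform
  if (!length(centroids$mz) || !length(candidates)) return(list())

  # exactly mass-degenerate candidates (e.g. N-terminal vs internal acetyl)
  # are indistinguishable at MS1 and collapse to one joint-labelled class
  masses <- vapply(candidates, proteoform_mass, numeric(1))
  groups <- match(round(masses, 6), unique(round(masses, 6)))
  candidates <- lapply(unique(groups), function(g) {
    members <- candidates[groups == g]
    p <- members[[1]]
    p$label <- paste(vapply(members, `[[`, character(1), "label"),
                     collapse = "/")
    p
  })

  # tentative matches across all (candidate, charge, isotopologue)
  tent <- list()
  for (ci in seq_along(candidates)) {
    p <- candidates[[ci]]
    pat <- isotope_distribution(apply_modifications(p, check_sites = FALSE))
    pat <- pat[pat$abundance >= min_isotopologue_frac * max(pat$abundance), ]
    for (z in charges) {
      mz_theo <- mz(pat$mass, z)
      idx <- findInterval(mz_theo, centroids$mz)
      for (k in seq_along(mz_theo)) {
        cand_pk <- unique(pmin(pmax(c(idx[k], idx[k] + 1L), 1L),
                               length(centroids$mz)))
        err <- ppm_error(centroids$mz[cand_pk], mz_theo[k])
        best <- which.min(abs(err))
        if (abs(err[best]) <= tol_ppm)
          tent[[length(tent) + 1L]] <- data.frame(
            cand = ci, charge = z, offset = pat$offset[k],
            mz_theoretical = mz_theo[k], peak = cand_pk[best],
            error_ppm = err[best])
      }
    }
  }
  if (!length(tent)) return(list())
  tent <- do.call(rbind, tent)
  tent <- tent[order(abs(tent$error_ppm)), , drop = FALSE]
  used <- logical(length(centroids$mz))
  taken <- logical(nrow(tent))
  for (i in seq_len(nrow(tent))) {
    if (!used[tent$peak[i]]) {
      used[tent$peak[i]] <- TRUE
      taken[i] <- TRUE
    }
  }
  tent <- tent[taken, , drop = FALSE]

  envs <- list()
  for (key in unique(paste(tent$cand, tent$charge))) {
    sub <- tent[paste(tent$cand, tent$charge) == key, , drop = FALSE]
    if (nrow(sub) < min_peaks) next
    sub <- sub[order(sub$offset), , drop = FALSE]
    peaks <- data.frame(offset = sub$offset,
                        mz_theoretical = sub$mz_theoretical,
                        mz_observed = centroids$mz[sub$peak],
                        intensity = centroids$intensity[sub$peak],
                        error_ppm = sub$error_ppm)
    envs[[length(envs) + 1L]] <- list(
      label = candidates[[sub$cand[1]]]$label,
      charge = sub$charge[1], peaks = peaks,
      intensity = sum(peaks$intensity))
  }
  envs
}

#' Relative abundances from assigned envelopes
#'
#' Implements envelope-integration quantification for intact proteoforms:
#' for each proteoform class, take its `n_charge` most intense charge-state
#' envelopes, in each sum the `top_k` most intense matched isotopic peaks,
#' sum those, and normalize the per-class sums to 100 percent. Classes seen
#' in fewer than `n_charge` charge states are kept and flagged (with the
#' shortfall recorded), never silently dropped.
#'
#' @param envelopes Envelope list from [assign_envelopes()].
#' @param top_k Isotopic peaks summed per charge state (default 4).
#' @param n_charge Charge states summed per class (default 3).
#' @return A data.frame with columns `label`, `abundance_percent`,
#'   `n_charge_states`, `flagged` (TRUE when fewer than `n_charge` charge
#'   states were available); abundances sum to 100.
#' @export
relative_abundance <- function(envelopes, top_k = 4, n_charge = 3) {
  if (!length(envelopes))
    return(data.frame(label = character(0), abundance_percent = numeric(0),
                      n_charge_states = integer(0), flagged = logical(0)))
  labels <- vapply(envelopes, `[[`, character(1), "label")
  rows <- lapply(unique(labels), function(lab) {
    group <- envelopes[labels == lab]
    topk_sum <- vapply(group, function(e) {
      ints <- sort(e$peaks$intensity, decreasing = TRUE)
      sum(ints[seq_len(min(top_k, length(ints)))])
    }, numeric(1))
    ord <- order(topk_sum, decreasing = TRUE)
    use <- ord[seq_len(min(n_charge, length(ord)))]
    data.frame(label = lab, raw = sum(topk_sum[use]),
               n_charge_states = length(unique(vapply(group, `[[`,
                                                      numeric(1), "charge"))),
               flagged = length(use) < n_charge)
  })
  out <- do.call(rbind, rows)
  out$abundance_percent <- out$raw / sum(out$raw) * 100
  out <- out[order(-out$abundance_percent), ,
             drop = FALSE][, c("label", "abundance_percent",
                               "n_charge_states", "flagged")]
  rownames(out) <- NULL
  out
}
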