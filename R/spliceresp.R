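#' Percent spliced in
#'
#' \code{PSI = 100 * included / (included + skipped)}, in molar units.
#'
#' @param included,skipped non-negative isoform quantities (vectorized).
#' @return PSI values in [0, 100].
#' @examples
#' computePsi(3, 1) # 75
#' @export
computePsi <- function(included, skipped) {
    if (any(included < 0 | skipped < 0))
        stop("isoform quantities must be >= 0")
    if (any(included + skipped == 0))
        stop("included and skipped both zero: no measurement")
    100 * included / (included + skipped)
}

#' Per-exon PSI means, knockdown deltas and tests
#'
#' Computes replicate PSI values from included/skipped quantities, averages
#' them per exon and condition, and for every knockdown condition present
#' contrasts it against control: \code{dPSI = mean PSI(kd) - mean
#' PSI(control)} with a two-sided independent two-sample t-test (pooled
#' variance, df = n1 + n2 - 2; Welch via \code{equalVar = FALSE}).
#' Contrasts with fewer than two replicates on either side are skipped with
#' a warning (their statistics are NA).
#'
#' @param measurements \code{data.frame} with columns \code{exon_id},
#'   \code{sample_id}, \code{condition} (control / kd_alpha / kd_beta /
#'   kd_double), \code{included}, \code{skipped}.
#' @param equalVar pooled-variance t-test (default TRUE).
#' @param adjust multiple-testing adjustment passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}; per-exon p
#'   values are reported unadjusted).
#' @return \code{data.frame}, one row per exon: \code{psi_<condition>}
#'   means, and per knockdown \code{dpsi_<kd>}, \code{t_<kd>},
#'   \code{p_<kd>}.
#' @export
deltaPsi <- function(measurements, equalVar = TRUE, adjust = "none") {
    req <- c("exon_id", "sample_id", "condition", "included", "skipped")
    if (!all(req %in% colnames(measurements)))
        stop("measurements need columns: ", paste(req, collapse = ", "))
    bad <- setdiff(unique(measurements$condition), .CONDITIONS)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    if (!"control" %in% measurements$condition)
        stop("control condition is required")
    measurements$psi <- computePsi(measurements$included,
                                   measurements$skipped)
    conds <- intersect(.CONDITIONS, unique(measurements$condition))
    kds <- setdiff(conds, "control")
    exons <- unique(measurements$exon_id)

    warned <- FALSE
    rows <- lapply(exons, function(ex) {
        mm <- measurements[measurements$exon_id == ex, ]
        byCond <- split(mm$psi, factor(mm$condition, conds))
        row <- list(exon_id = ex)
        for (cn in conds) row[[paste0("psi_", cn)]] <- mean(byCond[[cn]])
        for (kd in kds) {
            a <- byCond[[kd]]; ctl <- byCond[["control"]]
            row[[paste0("dpsi_", kd)]] <- mean(a) - mean(ctl)
            if (length(a) < 2L || length(ctl) < 2L) {
                if (!warned) {
                    warning("contrast(s) with < 2 replicates skipped")
                    warned <<- TRUE
                }
                row[[paste0("t_", kd)]] <- NA_real_
                row[[paste0("p_", kd)]] <- NA_real_
            } else {
                ht <- .tTest(a, ctl, equalVar = equalVar)
                row[[paste0("t_", kd)]] <- ht$t
                row[[paste0("p_", kd)]] <- ht$p
            }
        }
        as.data.frame(row, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (adjust != "none")
        for (kd in kds)
            out[[paste0("p_", kd)]] <- stats::p.adjust(
                out[[paste0("p_", kd)]], method = adjust)
    rownames(out) <- NULL
    out
}

#' Classify knockdown splicing responses
#'
#' Labels each exon from its double-knockdown PSI change and control
#' inclusion level: responsive when |dPSI(double)| exceeds
#' \code{responsiveThreshold} (and the contrast is significant when a p
#' value is available), strongly responsive when it additionally exceeds
#' \code{strongThreshold}, constitutive-like when control PSI is at least
#' \code{constitutiveThreshold}, fully constitutive at control PSI 100.
#' Non-responders are exons below the responsive threshold or without a
#' significant contrast.
#'
#' @param x output of \code{\link{deltaPsi}}, or a numeric vector of
#'   double-knockdown dPSI values.
#' @param psiControl control PSI means (used when \code{x} is a vector).
#' @param p double-knockdown p values (optional; NA skips the significance
#'   requirement, e.g. for externally quantified dPSI values).
#' @param responsiveThreshold PSI points, default 15 (exclusive).
#' @param strongThreshold PSI points, default 40 (exclusive).
#' @param constitutiveThreshold control PSI, default 95 (inclusive).
#' @param alpha significance level for the contrast, default 0.05.
#' @return \code{data.frame}: \code{exon_id}, \code{dpsi_double},
#'   logical columns \code{responsive}, \code{strong},
#'   \code{constitutive_like}, \code{fully_constitutive},
#'   \code{non_responder}, and a primary \code{class} label
#'   (strong_responder / responsive / non_responder).
#' @examples
#' classifyResponse(c(ANKRD1 = -73, SMYD2 = -5), psiControl = c(100, 90))
#' @export
classifyResponse <- function(x, psiControl = NULL, p = NULL,
                             responsiveThreshold = 15,
                             strongThreshold = 40,
                             constitutiveThreshold = 95, alpha = 0.05) {
    if (is.data.frame(x)) {
        if (!"dpsi_kd_double" %in% colnames(x))
            stop("double-knockdown dPSI is required for classification")
        dpsi <- x$dpsi_kd_double
        ids <- x$exon_id
        psiControl <- x$psi_control
        p <- x$p_kd_double
    } else {
        dpsi <- x
        ids <- if (!is.null(names(x))) names(x) else
            paste0("exon", seq_along(x))
    }
    if (is.null(psiControl)) psiControl <- rep(NA_real_, length(dpsi))
    if (is.null(p)) p <- rep(NA_real_, length(dpsi))
    sig <- is.na(p) | p < alpha
    responsive <- abs(dpsi) > responsiveThreshold & sig
    strong <- responsive & abs(dpsi) > strongThreshold
    constit <- !is.na(psiControl) & psiControl >= constitutiveThreshold
    fully <- !is.na(psiControl) & psiControl >= 100 - 1e-9
    data.frame(exon_id = ids, dpsi_double = dpsi,
               responsive = responsive, strong = strong,
               constitutive_like = constit, fully_constitutive = fully,
               non_responder = !responsive,
               class = ifelse(strong, "strong_responder",
                              ifelse(responsive, "responsive",
                                     "non_responder")),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Paralog-compensation test
#'
#' An exon is buffered by paralog compensation when joint depletion moves
#' its PSI far more than either single depletion: the buffering score is
#' \code{S = |dPSI(double)| - max(|dPSI(alpha)|, |dPSI(beta)|)} and the
#' exon is flagged when \code{S > minBuffer} and both single-knockdown
#' effects stay below \code{maxSingle} PSI points.
#'
#' @param x output of \code{\link{deltaPsi}} containing
#'   \code{dpsi_kd_alpha}, \code{dpsi_kd_beta} and \code{dpsi_kd_double},
#'   or a 3-column matrix/data.frame in that order.
#' @param minBuffer minimum buffering score (default 15).
#' @param maxSingle maximum single-knockdown |dPSI| (default 10).
#' @return \code{data.frame}: \code{exon_id}, \code{buffering_score},
#'   \code{compensated}. Exons with a missing condition get NA and a
#'   warning.
#' @export
compensationTest <- function(x, minBuffer = 15, maxSingle = 10) {
    need <- c("dpsi_kd_alpha", "dpsi_kd_beta", "dpsi_kd_double")
    if (!all(need %in% colnames(x))) {
        warning("missing knockdown condition(s); compensation not assessed")
        return(data.frame(exon_id = x$exon_id,
                          buffering_score = NA_real_, compensated = NA))
    }
    da <- abs(x$dpsi_kd_alpha); db <- abs(x$dpsi_kd_beta)
    dd <- abs(x$dpsi_kd_double)
    s <- dd - pmax(da, db)
    data.frame(exon_id = if ("exon_id" %in% colnames(x)) x$exon_id else
                   paste0("exon", seq_along(s)),
               buffering_score = s,
               compensated = s > minBuffer & da < maxSingle &
                   db < maxSingle,
               row.names = NULL, stringsAsFactors = FALSE)
}
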