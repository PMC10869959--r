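#' Hesitant fuzzy element of a method's evaluation criteria
#'
#' A hesitant fuzzy set attaches to each alternative (here: a feature-
#' selection method) a multiset of membership values in [0,1]. The
#' element used by this scoring system collects the six evaluation
#' criteria of a method: accuracy, AUC, F-score, MCC in its [0,1]
#' normalized form, precision (PPV) and recall. Order is irrelevant.
#'
#' @param values numeric vector of criterion values in [0,1].
#' @param method_id label of the method the element belongs to.
#' @return Object of class \code{"hfs_element"}.
#' @export
hfs_element <- function(values, method_id = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop("all hesitant-fuzzy values must lie in [0,1]")
  structure(list(method_id = method_id, values = values),
            class = "hfs_element")
}

#' Build the six-criterion hesitant fuzzy element from a profile
#'
#' @param profile an \code{\link{evaluation_profile}}.
#' @param method_id method label.
#' @param round_digits optional "table fidelity" rounding: round every
#'   criterion to this many digits before scoring (reproduces scores
#'   computed from a printed, rounded report). Default \code{NULL}: score
#'   the unrounded values.
#' @return An \code{\link{hfs_element}} with the six values
#'   \{ACC, AUC, F-score, normalized MCC, PPV, recall\}.
#' @export
build_hfs <- function(profile, method_id = "", round_digits = NULL) {
  stopifnot(inherits(profile, "evaluation_profile"))
  v <- c(profile$acc, profile$auc, profile$f_score,
         profile$mcc_normalized, profile$ppv, profile$recall)
  if (!is.null(round_digits)) v <- round(v, round_digits)
  hfs_element(v, method_id)
}

#' Deviation degree of a hesitant fuzzy element
#'
#' The pairwise-spread statistic
#' \deqn{\bar\sigma'(h) = \frac{1}{l_h}\sqrt{\sum_{(\gamma_i,\gamma_j)\in h}
#'   (\gamma_i-\gamma_j)^2}}
#' where the sum runs over all ordered pairs of element values (so each
#' unordered pair contributes twice) and \eqn{l_h} is the number of
#' values. It reflects the standard deviation among all pairs of
#' criteria: a method whose six criteria agree closely has a small
#' deviation degree.
#'
#' @param h an \code{\link{hfs_element}} with at least 2 values.
#' @return The deviation degree, a nonnegative number.
#' @examples
#' deviation_degree(hfs_element(c(0, 1)))  # sqrt(2)/2
#' @export
deviation_degree <- function(h) {
  stopifnot(inherits(h, "hfs_element"))
  v <- h$values
  l <- length(v)
  if (l < 2) stop("deviation degree needs at least 2 values")
  # explicit ordered-pair sum; l is small and this avoids the
  # cancellation the expanded closed form suffers on near-equal values
  ss <- sum(outer(v, v, "-")^2)
  sqrt(ss) / l
}

#' Score function of a hesitant fuzzy element
#'
#' SF(h) = 1 / deviation degree: the less the six criteria disagree, the
#' higher the method scores. A zero deviation degree (all criteria equal)
#' gives an infinite score with a warning — such a method is maximally
#' self-consistent and ranks first.
#'
#' @param h an \code{\link{hfs_element}}.
#' @return Object of class \code{"method_score"}: list with
#'   \code{method_id}, \code{deviation} and \code{score}.
#' @export
score_function <- function(h) {
  dev <- deviation_degree(h)
  if (dev == 0) {
    warning("deviation degree is 0; score is +Inf for method '",
            h$method_id, "'")
    sc <- Inf
  } else sc <- 1 / dev
  structure(list(method_id = h$method_id, deviation = dev, score = sc),
            class = "method_score")
}

#' Rank methods by their hesitant-fuzzy scores
#'
#' Orders method scores descending; ties broken by lexicographic method
#' id. The winner feeds the wrapper stage; the runner-up is kept for the
#' comparison arm.
#'
#' @param scores a list of \code{\link{score_function}} results.
#' @return A list with \code{table} (data frame of method_id, deviation,
#'   score in rank order), \code{winner} and \code{runner_up} (method ids;
#'   runner-up \code{NA} with a single method).
#' @export
rank_methods <- function(scores) {
  if (!length(scores)) stop("no scores to rank")
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(method_id = s$method_id, deviation = s$deviation,
               score = s$score)))
  df <- df[order(-df$score, df$method_id), , drop = FALSE]
  rownames(df) <- NULL
  list(table = df, winner = df$method_id[1],
       runner_up = if (nrow(df) > 1) df$method_id[2] else NA_character_)
}
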