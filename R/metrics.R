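#' Mean squared error
#'
#' @param y_true,y_hat Conformable numeric arrays.
#' @return Mean of squared differences over all entries.
#' @export
mse <- function(y_true, y_hat) {
  if (length(y_true) != length(y_hat)) stop("shape mismatch")
  mean((as.numeric(y_true) - as.numeric(y_hat))^2)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-agreement between two partitions, computed from
#' the pair-counting contingency formula. Invariant to label permutations
#' and defined for partitions with different numbers of classes; 1 means
#' identical partitions, around 0 means agreement at chance level.
#'
#' @param labels_a,labels_b Equal-length label vectors (any types that can
#'   be treated as factors).
#' @return Scalar in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  stopifnot(n >= 2L)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Classification error rate
#'
#' @param y_true,y_hat_class Conformable arrays of class labels.
#' @return Fraction of misclassified entries.
#' @export
error_rate <- function(y_true, y_hat_class) {
  if (length(y_true) != length(y_hat_class)) stop("shape mismatch")
  mean(as.numeric(y_true) != as.numeric(y_hat_class))
}
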