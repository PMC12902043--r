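# Round half away from zero (the convention of the reported tables, unlike
# base round()'s round-half-even). Only used on non-negative quantities.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

check_records <- function(records, require_true = TRUE) {
  need <- c("image_id", "modality", "evaluator", "assigned_species")
  if (require_true) need <- c(need, "true_species")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("degenerate input: empty record set", call. = FALSE)
  invisible(records)
}

#' Classification accuracy in percent
#'
#' Fraction of records whose assigned species equals the true species,
#' expressed in percent and rounded half-up to one decimal (the convention
#' of the study tables; 45/48 prints as 93.8).
#'
#' @param records Evaluation records with `true_species` and
#'   `assigned_species` columns.
#' @return A single number, percent to one decimal.
#' @examples
#' r <- pollen_study_records()
#' accuracy_percent(r[r$modality == "DIHM" & r$evaluator == "expert1", ])
#' @export
accuracy_percent <- function(records) {
  check_records(records)
  round_half_up(100 * mean(records$assigned_species == records$true_species),
                1L)
}

#' Pooled classification accuracy
#'
#' Pools several record sets by summing correct and total counts before
#' forming the percentage — never by averaging already-rounded
#' percentages, which differs in the final decimal (e.g. 47/48 and 45/48
#' pool to 92/96 = 95.8, while the rounded per-set values average to
#' 95.85).
#'
#' @param ... Record data.frames, or a single list of them, or one
#'   already-combined data.frame.
#' @return Pooled accuracy in percent, one decimal.
#' @export
pooled_accuracy <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  records <- do.call(rbind, args)
  check_records(records)
  accuracy_percent(records)
}

#' Build a confusion matrix from evaluation records
#'
#' Counts assignments with rows indexing the true class and columns the
#' assigned class, over the fixed six-class vocabulary. With
#' `normalise = TRUE` a row-stochastic `proportions` matrix is attached;
#' classes with no records keep an all-zero row and are flagged in the
#' `empty_classes` element.
#'
#' @param records Evaluation records.
#' @param normalise Logical; also compute row-normalised proportions.
#' @param classes Ordered class vocabulary (default [pollen_classes()]).
#' @return An object of class `confusion_matrix` with elements `classes`,
#'   `counts`, and (if requested) `proportions` and `empty_classes`.
#' @export
build_confusion <- function(records, normalise = FALSE,
                            classes = pollen_classes()) {
  check_records(records)
  unknown <- setdiff(unique(c(records$true_species,
                              records$assigned_species)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(records$true_species, levels = classes),
                  factor(records$assigned_species, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(true = classes, assigned = classes))
  out <- list(classes = classes, counts = counts)
  if (isTRUE(normalise)) {
    rs <- rowSums(counts)
    props <- counts / ifelse(rs == 0, 1, rs)
    out$proportions <- props
    out$empty_classes <- classes[rs == 0]
  }
  structure(out, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = assigned\n")
  print(x$counts)
  invisible(x)
}

#' Per-class F1 scores from a confusion matrix
#'
#' For each class `c`: `TP = counts[c, c]`, `FP` the rest of its column,
#' `FN` the rest of its row, and `F1 = 2 TP / (2 TP + FP + FN)`, rounded
#' half-up to three decimals. A class with a zero denominator (no true or
#' assigned instances) scores 0 and is listed in the `empty_classes`
#' attribute.
#'
#' @param cm A [build_confusion()] result.
#' @return Named numeric vector of F1 scores.
#' @export
per_class_f1 <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    stop("cm must be a confusion_matrix", call. = FALSE)
  counts <- cm$counts
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, round_half_up(2 * tp / pmax(denom, 1), 3L))
  names(f1) <- cm$classes
  attr(f1, "empty_classes") <- cm$classes[denom == 0]
  f1
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where
#' `p_o` is the observed fraction of identical labels and
#' `p_e = sum_c p_a(c) p_b(c)` the agreement expected from the two raters'
#' marginal label frequencies. Accepts two aligned label vectors, or two
#' record data.frames which are aligned by `image_id` (every id must match
#' one-to-one). When `p_e = 1` (both raters constant on the same label)
#' kappa is 1 if agreement is perfect and undefined otherwise.
#'
#' @param a,b Character/factor label vectors of equal length, or record
#'   data.frames with `image_id` and `assigned_species`.
#' @return An object of class `agreement_result` with `kappa`,
#'   `observed_agreement`, `expected_agreement` and `n_pairs`.
#' @examples
#' cohen_kappa(c("x", "x", "x", "y"), c("x", "x", "y", "y"))$kappa  # 0.5
#' @export
cohen_kappa <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    if (!is.data.frame(a) || !is.data.frame(b))
      stop("a and b must both be vectors or both record data.frames",
           call. = FALSE)
    check_records(a, require_true = FALSE)
    check_records(b, require_true = FALSE)
    if (anyDuplicated(a$image_id) || anyDuplicated(b$image_id))
      stop("image_id must be unique within each record set", call. = FALSE)
    if (!setequal(a$image_id, b$image_id))
      stop("unmatched image_ids between the two record sets", call. = FALSE)
    b <- b[match(a$image_id, b$image_id), ]
    a <- a$assigned_species
    b <- b$assigned_species
  }
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 1L) stop("degenerate input: empty label vectors", call. = FALSE)
  labs <- sort(unique(c(a, b)))
  p_o <- mean(a == b)
  pa <- table(factor(a, levels = labs)) / n
  pb <- table(factor(b, levels = labs)) / n
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) kappa <- 1
    else stop("kappa undefined: expected agreement is 1 but observed is not",
              call. = FALSE)
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(
    list(kappa = kappa, observed_agreement = p_o, expected_agreement = p_e,
         n_pairs = n),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
    x$kappa, x$observed_agreement, x$expected_agreement, x$n_pairs))
  invisible(x)
}

# Align one evaluator pair (or modality pair) and return kappa.
kappa_between <- function(records, split_col, v1, v2, subset = TRUE) {
  r <- records[subset, , drop = FALSE]
  a <- r[r[[split_col]] == v1, c("image_id", "modality", "evaluator",
                                 "assigned_species")]
  b <- r[r[[split_col]] == v2, c("image_id", "modality", "evaluator",
                                 "assigned_species")]
  # a single image_id can appear in several modalities; build a pair key
  key_cols <- setdiff(c("image_id", "modality", "evaluator"), split_col)
  a$key <- do.call(paste, c(a[key_cols], sep = "|"))
  b$key <- do.call(paste, c(b[key_cols], sep = "|"))
  idx <- match(a$key, b$key)
  if (anyNA(idx) || nrow(a) != nrow(b))
    stop("unmatched records between ", v1, " and ", v2, call. = FALSE)
  b <- b[idx, ]
  cohen_kappa(a$assigned_species, b$assigned_species)
}

#' Summary table of a reading study
#'
#' Computes the study's headline statistics from a full record set:
#' per-evaluator and pooled accuracy for every modality, inter-observer
#' Cohen's kappa per modality and overall (when exactly two evaluators are
#' present), and inter-modality kappa per evaluator and overall (when
#' exactly two modalities are present, pairing each evaluator's labels on
#' matched image content). Accuracies are percent to one decimal; kappas
#' are unrounded.
#'
#' @param records Evaluation records covering at least one evaluator and
#'   modality.
#' @return A tidy data.frame with columns `metric`, `modality`,
#'   `evaluator`, `value`.
#' @examples
#' summarize_study(pollen_study_records())
#' @export
summarize_study <- function(records) {
  check_records(records)
  modalities <- unique(records$modality)
  evaluators <- unique(records$evaluator)
  rows <- list()
  add <- function(metric, modality, evaluator, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, modality = modality, evaluator = evaluator,
      value = value, stringsAsFactors = FALSE)

  for (m in modalities) {
    for (ev in evaluators) {
      sel <- records$modality == m & records$evaluator == ev
      if (any(sel))
        add("accuracy", m, ev, accuracy_percent(records[sel, ]))
    }
    add("pooled_accuracy", m, "all",
        accuracy_percent(records[records$modality == m, ]))
  }
  if (length(evaluators) == 2L) {
    for (m in modalities)
      add("kappa_interobserver", m, "pair",
          kappa_between(records, "evaluator", evaluators[1], evaluators[2],
                        records$modality == m)$kappa)
    add("kappa_interobserver", "all", "pair",
        kappa_between(records, "evaluator", evaluators[1],
                      evaluators[2])$kappa)
  }
  if (length(modalities) == 2L) {
    for (ev in evaluators)
      add("kappa_intermodality", "pair", ev,
          kappa_between(records, "modality", modalities[1], modalities[2],
                        records$evaluator == ev)$kappa)
    add("kappa_intermodality", "pair", "all",
        kappa_between(records, "modality", modalities[1],
                      modalities[2])$kappa)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
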