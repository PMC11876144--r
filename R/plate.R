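#' KASP plate records and feature vectors
#'
#' A KASP assay plate is read out as endpoint fluorescence in two channels:
#' relative HEX signal `x` (allele 1 reporter) and relative FAM signal `y`
#' (allele 2 reporter), one pair per well. A plate holds 96 wells: 94 DNA
#' sample wells and 2 no-template controls (NTC). Wells may carry a genotype
#' assignment (`AA`, `BB`, `AB` or `unknown`) and the plate an expert
#' typing-effect score in `{0, 10, ..., 100}`.
#'
#' @param snp_id character identifier of the SNP assay.
#' @param wells data frame with numeric columns `x`, `y`, character columns
#'   `role` (`"DNA"` or `"NTC"`) and `genotype`
#'   (`"AA"`, `"BB"`, `"AB"` or `"unknown"`).
#' @param label optional integer score, a multiple of 10 in `[0, 100]`.
#' @return an object of class `kasp_plate`.
#' @examples
#' p <- sample_plate(default_spec(100), seed = 1)
#' p
#' @export
kasp_plate <- function(snp_id, wells, label = NULL) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L)
  wells <- as.data.frame(wells)
  if (!all(c("x", "y", "role") %in% names(wells))) {
    stop_talsrx("plate '%s': wells need columns x, y, role", snp_id)
  }
  if (is.null(wells$genotype)) wells$genotype <- "unknown"
  wells <- wells[, c("x", "y", "role", "genotype")]
  plate <- structure(
    list(snp_id = snp_id, wells = wells,
         label = if (is.null(label) || is.na(label[1])) NULL
                 else as.integer(label)),
    class = "kasp_plate")
  validate_plate(plate)
  plate
}

validate_plate <- function(plate) {
  w <- plate$wells
  if (nrow(w) != 96L) {
    stop_talsrx("plate '%s': expected 96 wells, got %d", plate$snp_id, nrow(w))
  }
  if (sum(w$role == "NTC") != 2L) {
    stop_talsrx("plate '%s': expected exactly 2 NTC wells, got %d",
                plate$snp_id, sum(w$role == "NTC"))
  }
  if (any(!is.finite(w$x)) || any(!is.finite(w$y)) ||
      any(w$x < 0) || any(w$y < 0)) {
    stop_talsrx("plate '%s': fluorescence values must be finite and >= 0",
                plate$snp_id)
  }
  if (!all(w$genotype %in% c("AA", "BB", "AB", "unknown"))) {
    stop_talsrx("plate '%s': invalid genotype code", plate$snp_id)
  }
  if (!is.null(plate$label)) check_score(plate$label)
  invisible(plate)
}

check_score <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)) ||
      any(score %% 10 != 0) || any(score < 0) || any(score > 100)) {
    stop_talsrx("score must be a multiple of 10 in [0, 100], got %s",
                paste(score, collapse = ", "))
  }
  invisible(as.integer(score))
}

#' @export
print.kasp_plate <- function(x, ...) {
  lab <- if (is.null(x$label)) "unlabelled" else paste0("score ", x$label)
  geno <- table(x$wells$genotype[x$wells$role == "DNA"])
  cat(sprintf("<kasp_plate> %s  (%s)\n", x$snp_id, lab))
  cat("  DNA wells:", sum(x$wells$role == "DNA"),
      " NTC wells:", sum(x$wells$role == "NTC"), "\n")
  cat("  genotypes:", paste(names(geno), geno, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Plot the two-channel scatter of a plate
#'
#' @param x a `kasp_plate`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kasp_plate <- function(x, ...) {
  w <- x$wells
  cols <- c(AA = "#d95f02", BB = "#1b9e77", AB = "#7570b3", unknown = "grey40")
  pch <- ifelse(w$role == "NTC", 4L, 19L)
  graphics::plot(w$x, w$y, col = cols[w$genotype], pch = pch,
                 xlab = "relative HEX signal (x)",
                 ylab = "relative FAM signal (y)",
                 main = x$snp_id, ...)
  invisible(x)
}

#' Build the 192-value feature vector of a plate
#'
#' Wells are serialised in fixed order — the 94 DNA wells in plate order
#' first, then the 2 NTC wells — with the two channels interleaved per well:
#' `(x_1, y_1, x_2, y_2, ...)`, giving `2 x 96 = 192` values.
#'
#' @param plate a [kasp_plate()].
#' @return numeric vector of length 192.
#' @export
build_feature_vector <- function(plate) {
  validate_plate(plate)
  w <- plate$wells
  ord <- c(which(w$role == "DNA"), which(w$role == "NTC"))
  as.numeric(rbind(w$x[ord], w$y[ord]))
}

#' Encode a typing-effect score as a class index (and back)
#'
#' The eleven rubric scores `{0, 10, ..., 100}` map bijectively onto class
#' indices `0..10` by division by ten.
#'
#' @param score integer vector of scores, multiples of 10 in `[0, 100]`.
#' @param class_index integer vector of class indices in `0..10`.
#' @return `encode_label`: integer class indices; `decode_label`: scores.
#' @export
encode_label <- function(score) {
  check_score(score)
  as.integer(score) %/% 10L
}

#' @rdname encode_label
#' @export
decode_label <- function(class_index) {
  if (!is.numeric(class_index) || any(!is.finite(class_index)) ||
      any(class_index != round(class_index)) ||
      any(class_index < 0) || any(class_index > 10)) {
    stop_talsrx("class index must be an integer in 0..10")
  }
  as.integer(class_index) * 10L
}

n_score_classes <- function() 11L

#' Construct a dataset of KASP plates
#'
#' @param records list of [kasp_plate()] objects.
#' @return an object of class `kasp_dataset`.
#' @seealso [generate_dataset()], [read_plate_table()]
#' @export
kasp_dataset <- function(records) {
  stopifnot(is.list(records))
  for (r in records) {
    if (!inherits(r, "kasp_plate")) stop_talsrx("records must be kasp_plate")
  }
  structure(list(records = records), class = "kasp_dataset")
}

#' @export
length.kasp_dataset <- function(x) length(x$records)

#' @export
print.kasp_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<kasp_dataset> %d plates\n", length(x)))
  if (all(is.na(labs))) {
    cat("  unlabelled\n")
  } else {
    tab <- table(labs, useNA = "no")
    cat("  scores:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Feature matrix and labels of a dataset
#'
#' @param dataset a [kasp_dataset()].
#' @return `feature_matrix`: numeric `n x 192` matrix; `dataset_labels`:
#'   integer score vector with `NA` for unlabelled plates.
#' @export
feature_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "kasp_dataset"))
  X <- t(vapply(dataset$records, build_feature_vector, numeric(192)))
  rownames(X) <- vapply(dataset$records, function(r) r$snp_id, character(1))
  colnames(X) <- sprintf("f%03d", seq_len(192))
  X
}

#' @rdname feature_matrix
#' @export
dataset_labels <- function(dataset) {
  stopifnot(inherits(dataset, "kasp_dataset"))
  vapply(dataset$records, function(r) {
    if (is.null(r$label)) NA_integer_ else r$label
  }, integer(1))
}

# rebuild a plate from one 192-value feature row (DNA wells 1..94, NTC 95..96)
plate_from_features <- function(snp_id, values, label = NULL) {
  if (length(values) != 192L) {
    stop_talsrx("plate '%s': expected 192 feature values, got %d",
                snp_id, length(values))
  }
  m <- matrix(values, nrow = 2L) # row 1 = x, row 2 = y
  kasp_plate(snp_id,
             data.frame(x = m[1, ], y = m[2, ],
                        role = c(rep("DNA", 94), rep("NTC", 2)),
                        genotype = "unknown"),
             label = label)
}

#' Read / write a plate table
#'
#' Plate tables are comma-delimited text with a header row and columns
#' `snp_id`, `f001` ... `f192` (the interleaved feature values of
#' [build_feature_vector()]) and an optional `label` column. Writing then
#' reading a dataset reproduces its feature matrix up to text round-off;
#' genotype assignments are not stored in the table.
#'
#' @param path file path.
#' @param dataset a [kasp_dataset()].
#' @return `read_plate_table`: a [kasp_dataset()].
#' @export
read_plate_table <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"snp_id" %in% names(tab)) {
    stop_talsrx("plate table '%s': missing snp_id column", path)
  }
  has_label <- "label" %in% names(tab)
  feat_cols <- setdiff(names(tab), c("snp_id", "label"))
  if (length(feat_cols) != 192L) {
    stop_talsrx("plate table '%s': expected 192 feature columns, found %d",
                path, length(feat_cols))
  }
  for (j in feat_cols) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1]
      stop_talsrx("plate table '%s': non-numeric value in column %s, row %d",
                  path, j, bad %||% 1L)
    }
  }
  records <- lapply(seq_len(nrow(tab)), function(i) {
    plate_from_features(as.character(tab$snp_id[i]),
                        as.numeric(tab[i, feat_cols]),
                        label = if (has_label) tab$label[i] else NULL)
  })
  kasp_dataset(records)
}

#' @rdname read_plate_table
#' @export
write_plate_table <- function(dataset, path) {
  X <- feature_matrix(dataset)
  labs <- dataset_labels(dataset)
  tab <- data.frame(snp_id = rownames(X), X, check.names = FALSE)
  if (!all(is.na(labs))) tab$label <- labs
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into training and test parts
#'
#' Stratified by score label when labels are present: the training size is
#' the round-half-up of `n * train_frac`, allocated across classes by largest
#' remainder so per-class proportions are preserved within one record.
#' Classes with fewer than two members trigger a warning and an unstratified
#' split.
#'
#' @param dataset a [kasp_dataset()].
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with elements `train` and `test`, both `kasp_dataset`.
#' @export
split_dataset <- function(dataset, train_frac = 0.84, seed = 1L) {
  stopifnot(inherits(dataset, "kasp_dataset"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop_talsrx("train_frac must be in (0, 1)")
  }
  n <- length(dataset)
  labs <- dataset_labels(dataset)
  n_train <- round_half_up(n * train_frac)
  stratify <- !any(is.na(labs))
  if (stratify && any(table(labs) < 2L)) {
    warning("a class has fewer than 2 members; falling back to unstratified split")
    stratify <- FALSE
  }
  set.seed(seed)
  if (stratify) {
    classes <- sort(unique(labs))
    ideal <- vapply(classes, function(cl) sum(labs == cl), numeric(1)) *
      train_frac
    base <- floor(ideal)
    rem <- n_train - sum(base)
    extra_order <- order(ideal - base, decreasing = TRUE)
    take <- base
    if (rem > 0) take[extra_order[seq_len(rem)]] <- take[extra_order[seq_len(rem)]] + 1
    train_idx <- unlist(lapply(seq_along(classes), function(k) {
      pool <- which(labs == classes[k])
      sample(pool, size = min(take[k], length(pool)))
    }))
  } else {
    train_idx <- sample(n, size = n_train)
  }
  train_idx <- sort(train_idx)
  list(train = kasp_dataset(dataset$records[train_idx]),
       test = kasp_dataset(dataset$records[setdiff(seq_len(n), train_idx)]))
}
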