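#' Default developmental stage order
#'
#' Egg, four larval instars, pupa, adult: the stage structure of a typical
#' lepidopteran rearing study censused daily.
#'
#' @export
DEFAULT_STAGES <- c("egg", "L1", "L2", "L3", "L4", "pupa", "adult")

#' Construct and validate a cohort of individual life histories
#'
#' A cohort is the raw input of the whole demographic analysis: one row per
#' individual per day of life, recording the developmental stage occupied,
#' whether the individual was alive at the daily census, and the number of
#' eggs laid that day.  Age is counted in integer days from 0, age 0 being
#' the day the egg was laid; each row represents the end-of-day state.
#'
#' @param data data.frame with columns `individual_id`, `sex`
#'   (`"female"`, `"male"` or `"undetermined"`), `age` (integer days >= 0),
#'   `stage`, `alive` (logical) and `eggs` (non-negative integer).
#' @param stage_order character vector of stage codes in developmental
#'   order; the last element is the adult stage.
#' @param label treatment name attached to the cohort.
#' @param allow_stage_skip if `TRUE`, an individual may jump over
#'   intermediate stages between consecutive days (off by default: a skip
#'   usually indicates a recording error).
#'
#' @details Validation enforces, per individual: consecutive ages starting
#'   at 0 with one row per day while alive; a non-decreasing stage sequence
#'   along `stage_order` with no stage re-entered; eggs only from adult
#'   females; sex `"undetermined"` only for individuals dead before the
#'   pupal stage (sex is determined morphologically at pupation).  A single
#'   terminal row with `alive = FALSE` is permitted to mark the day an
#'   individual was found dead; it contributes nothing to any count.
#'
#' @return object of class `cohort`: the validated data.frame, ordered by
#'   individual then age, with attributes `stage_order` and `label`.
#' @seealso [read_cohort()], [simulate_cohort()], [age_stage_counts()]
#' @export
cohort <- function(data, stage_order = DEFAULT_STAGES, label = "cohort",
                   allow_stage_skip = FALSE) {
  required <- c("individual_id", "sex", "age", "stage", "alive", "eggs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[required]
  data$individual_id <- as.character(data$individual_id)
  data$sex <- as.character(data$sex)
  data$stage <- as.character(data$stage)
  data$age <- as.integer(data$age)
  data$alive <- as.logical(data$alive)
  data$eggs <- as.integer(data$eggs)
  if (nrow(data) == 0L) stop("cohort must contain at least one individual",
                             call. = FALSE)
  data <- data[order(data$individual_id, data$age), , drop = FALSE]
  rownames(data) <- NULL

  validate_cohort_frame(data, stage_order, allow_stage_skip)

  structure(data,
            stage_order = stage_order,
            label = label,
            class = c("cohort", "data.frame"))
}

# One pass of invariant checks; errors name the individual and the rule.
validate_cohort_frame <- function(data, stage_order, allow_stage_skip) {
  adult <- stage_order[length(stage_order)]
  # sexing happens at pupation; with no pupal stage configured (collapsed
  # stage lists) only the adult stage forces a determined sex
  sexing_from <- if ("pupa" %in% stage_order) {
    match("pupa", stage_order)
  } else {
    length(stage_order)
  }
  pupal_or_later <- stage_order[seq(sexing_from, length(stage_order))]
  bad_stage <- setdiff(unique(data$stage), stage_order)
  if (length(bad_stage) > 0L) {
    stop("unknown stage code(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$sex %in% c("female", "male", "undetermined"))) {
    stop("sex must be one of female, male, undetermined", call. = FALSE)
  }
  if (any(is.na(data$age)) || any(data$age < 0L)) {
    stop("ages must be non-negative integers", call. = FALSE)
  }
  if (any(is.na(data$eggs)) || any(data$eggs < 0L)) {
    stop("egg counts must be non-negative integers", call. = FALSE)
  }
  fail <- function(id, rule) {
    stop(sprintf("individual '%s': %s", id, rule), call. = FALSE)
  }
  for (rows in split(seq_len(nrow(data)), data$individual_id)) {
    id <- data$individual_id[rows[1L]]
    age <- data$age[rows]
    alive <- data$alive[rows]
    stg <- match(data$stage[rows], stage_order)
    if (!identical(age, seq.int(0L, length.out = length(age)))) {
      fail(id, "ages must be consecutive integers starting at 0")
    }
    n_dead <- sum(!alive)
    if (n_dead > 1L || (n_dead == 1L && alive[length(alive)] == FALSE &&
                        any(!alive[-length(alive)]))) {
      fail(id, "only a single terminal row may have alive = FALSE")
    }
    if (n_dead == 1L && alive[length(alive)]) {
      fail(id, "a dead row must be the last observation")
    }
    dstg <- diff(stg)
    if (any(dstg < 0L)) {
      fail(id, "stage sequence must be non-decreasing (no stage re-entry)")
    }
    if (!allow_stage_skip && any(dstg > 1L)) {
      fail(id, "stage skipping is not permitted under this configuration")
    }
    if (length(unique(data$sex[rows])) != 1L) {
      fail(id, "sex must be constant within an individual")
    }
    sex <- data$sex[rows[1L]]
    egg_rows <- data$eggs[rows] > 0L
    if (any(egg_rows & !(sex == "female" &
                         data$stage[rows] == adult & alive))) {
      fail(id, "eggs may only be laid by live adult females")
    }
    if (sex == "undetermined" &&
        any(data$stage[rows] %in% pupal_or_later & alive)) {
      fail(id, "sex may be undetermined only for pre-pupal deaths")
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d individuals, %d individual-days, stages %s>\n",
              attr(x, "label"), cohort_size(x), sum(x$alive),
              paste(attr(x, "stage_order"), collapse = " > ")))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param x a [cohort()]
#' @return integer count of individuals (initial eggs)
#' @export
cohort_size <- function(x) length(unique(x$individual_id))

#' Read a cohort from its canonical long CSV
#'
#' The canonical format has header
#' `individual_id,sex,age,stage,alive,eggs`, UTF-8, comma-separated, one
#' row per individual-day.
#'
#' @inheritParams cohort
#' @param path path to a CSV file.
#' @return validated [cohort()]
#' @export
read_cohort <- function(path, stage_order = DEFAULT_STAGES,
                        label = NULL, allow_stage_skip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- tryCatch(
    utils::read.csv(path, colClasses = c(
      individual_id = "character", sex = "character", age = "integer",
      stage = "character", alive = "logical", eggs = "integer")),
    error = function(e) {
      stop("failed to parse cohort CSV '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  bad <- which(is.na(data$age) | is.na(data$alive) | is.na(data$eggs))
  if (length(bad) > 0L) {
    stop("malformed cohort row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  cohort(data, stage_order = stage_order,
         label = if (is.null(label)) basename(path) else label,
         allow_stage_skip = allow_stage_skip)
}

#' Write a cohort to the canonical long CSV
#'
#' Output is byte-stable under a fixed field ordering, so
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param x a [cohort()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)[c("individual_id", "sex", "age", "stage",
                           "alive", "eggs")]
  df <- df[order(df$individual_id, df$age), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a bioassay cumulative-mortality table
#'
#' Expected header: `strain,concentration,replicate,day,n_total,n_dead_cum`
#' with one row per strain x concentration x replicate x day; cumulative
#' deaths must be non-decreasing over days within a series and never exceed
#' the number of insects exposed.
#'
#' @param path CSV path
#' @return validated data.frame of class `bioassay_table`
#' @export
read_bioassay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, colClasses = c(
    strain = "character", concentration = "numeric", replicate = "integer",
    day = "integer", n_total = "integer", n_dead_cum = "integer"))
  bioassay_table(data)
}

#' @rdname read_bioassay
#' @param data data.frame already holding the bioassay columns
#' @export
bioassay_table <- function(data) {
  required <- c("strain", "concentration", "replicate", "day",
                "n_total", "n_dead_cum")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("bioassay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("bioassay table is empty", call. = FALSE)
  if (any(data$day < 1L)) stop("days must be >= 1", call. = FALSE)
  if (any(data$n_dead_cum > data$n_total)) {
    stop("cumulative deaths exceed the number exposed", call. = FALSE)
  }
  if (any(data$n_dead_cum < 0L) || any(data$n_total <= 0L)) {
    stop("counts must be non-negative with n_total > 0", call. = FALSE)
  }
  key <- interaction(data$strain, data$concentration, data$replicate,
                     drop = TRUE)
  for (rows in split(seq_len(nrow(data)), key)) {
    ord <- rows[order(data$day[rows])]
    if (is.unsorted(data$n_dead_cum[ord])) {
      stop("cumulative mortality decreases over days for strain '",
           data$strain[rows[1L]], "', concentration ",
           data$concentration[rows[1L]], ", replicate ",
           data$replicate[rows[1L]], call. = FALSE)
    }
  }
  class(data) <- c("bioassay_table", "data.frame")
  data
}

#' Write a bioassay table to CSV
#' @param x a `bioassay_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bioassay <- function(x, path) {
  stopifnot(inherits(x, "bioassay_table"))
  df <- as.data.frame(x)[c("strain", "concentration", "replicate", "day",
                           "n_total", "n_dead_cum")]
  df <- df[order(df$strain, df$concentration, df$replicate, df$day), ,
           drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age-stage count matrix
#'
#' Tallies `n_xj`, the number of individuals alive in stage `j` at age `x`.
#' The adult stage is split into `adult_female` and `adult_male` columns;
#' all pre-adult stages pool the sexes (individuals dying before pupation
#' have undetermined sex and are retained).
#'
#' @param x a [cohort()]
#' @return integer matrix with one row per age (0-based, rownames give the
#'   age) and one column per stage; `sum(counts[1, ])` equals the cohort
#'   size.
#' @export
age_stage_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  stage_order <- attr(x, "stage_order")
  adult <- stage_order[length(stage_order)]
  cols <- c(stage_order[-length(stage_order)],
            "adult_female", "adult_male")
  live <- x[x$alive, , drop = FALSE]
  stage_col <- ifelse(live$stage == adult,
                      ifelse(live$sex == "female",
                             "adult_female", "adult_male"),
                      live$stage)
  ages <- 0:max(live$age)
  counts <- matrix(0L, nrow = length(ages), ncol = length(cols),
                   dimnames = list(age = ages, stage = cols))
  tab <- table(factor(live$age, levels = ages),
               factor(stage_col, levels = cols))
  counts[] <- as.integer(tab)
  counts
}
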