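#' Variable specification
#'
#' A `variable_spec` describes one covariate of the behavioral cohort table:
#' its measurement scale, levels, reference level, how it enters the Cox
#' design matrix and how it is encoded for the neural-network influence
#' analysis, plus the parameters the synthetic generator draws from.
#'
#' @param name Variable name (identifier).
#' @param scale One of `"binary"`, `"ordinal"`, `"nominal"`, `"continuous"`.
#' @param levels Ordered character vector of level labels (empty for
#'   continuous variables).
#' @param reference_level Reference level label; must be one of `levels`
#'   (unused for continuous variables).
#' @param cox_encoding How the variable enters the Cox design:
#'   `"binary_indicator"`, `"ordinal_numeric"`, `"dummy_set"` or
#'   `"continuous"` (identity pass-through).
#' @param ann_encoding How the variable is encoded for the ANN:
#'   `"binary_indicator"`, `"one_hot"`, `"minmax_continuous"` or
#'   `"top_category"` (highest intake level vs all lower levels).
#' @param gen_params For categorical scales, a named numeric vector of level
#'   probabilities summing to 1; for continuous scales, a length-2 numeric
#'   range `c(lo, hi)` with `lo < hi`.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, scale, levels = character(),
                          reference_level = NULL,
                          cox_encoding, ann_encoding, gen_params) {
  scale <- match.arg(scale, c("binary", "ordinal", "nominal", "continuous"))
  if (scale == "continuous") {
    if (length(gen_params) != 2 || gen_params[1] >= gen_params[2])
      stop("continuous variable '", name,
           "' needs gen_params = c(lo, hi) with lo < hi")
  } else {
    if (length(levels) < 2)
      stop("variable '", name, "' needs at least 2 levels")
    if (is.null(reference_level) || !reference_level %in% levels)
      stop("reference_level of '", name, "' must be one of its levels")
    if (abs(sum(gen_params) - 1) > 1e-12)
      stop("level probabilities of '", name, "' must sum to 1")
    if (length(gen_params) != length(levels))
      stop("gen_params of '", name, "' must match levels")
    names(gen_params) <- levels
  }
  structure(
    list(name = name, scale = scale, levels = as.character(levels),
         reference_level = reference_level,
         cox_encoding = cox_encoding, ann_encoding = ann_encoding,
         gen_params = gen_params),
    class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s; cox=%s, ann=%s)\n",
              x$name, x$scale, x$cox_encoding, x$ann_encoding))
  invisible(x)
}

bin_spec <- function(name, p1, ann = "binary_indicator") {
  variable_spec(name, "binary", levels = c("0", "1"), reference_level = "0",
                cox_encoding = "binary_indicator", ann_encoding = ann,
                gen_params = c(1 - p1, p1))
}

#' Default 18-predictor behavioral schema
#'
#' The laboratory-free predictor set used throughout the package: binary
#' psychosocial, sleep, gaming and smoking flags, ordinal salt intake,
#' nominal bread and cereal types, six-level processed-meat and beef
#' frequency scales, and continuous age and BMI.  Reference levels follow
#' epidemiological convention (never/absent/lowest intake; wholewheat for
#' bread, bran for cereal).
#'
#' Level probabilities are plausible mid-life UK population defaults for the
#' synthetic generator; they are tunable and make no claim to match any
#' particular cohort's marginals.
#'
#' @return A named list of [variable_spec()] objects (18 predictors).
#' @export
default_schema <- function() {
  freq6 <- c("never", "lt_once_week", "once_week", "two_to_four_week",
             "five_to_six_week", "daily")
  specs <- list(
    bin_spec("loneliness_isolation", 0.18),
    bin_spec("seen_psychiatrist", 0.11),
    bin_spec("sleeplessness_insomnia", 0.28),
    bin_spec("fed_up_feelings", 0.40),
    bin_spec("tense_highly_strung", 0.17),
    bin_spec("sleep_duration_7_8h", 0.55),
    bin_spec("nap_during_day", 0.38),
    bin_spec("difficulty_getting_up", 0.30),
    bin_spec("plays_computer_games", 0.25),
    bin_spec("current_tobacco_smoking", 0.10),
    variable_spec("smoking_status", "nominal",
                  levels = c("never", "previous", "current"),
                  reference_level = "never",
                  cox_encoding = "dummy_set", ann_encoding = "ever_never",
                  gen_params = c(0.55, 0.35, 0.10)),
    variable_spec("salt_added_to_food", "ordinal",
                  levels = c("never_rarely", "sometimes", "usually", "always"),
                  reference_level = "never_rarely",
                  cox_encoding = "ordinal_numeric", ann_encoding = "minmax_continuous",
                  gen_params = c(0.55, 0.25, 0.12, 0.08)),
    variable_spec("bread_type", "nominal",
                  levels = c("wholewheat", "brown", "white", "other"),
                  reference_level = "wholewheat",
                  cox_encoding = "dummy_set", ann_encoding = "one_hot",
                  gen_params = c(0.35, 0.20, 0.35, 0.10)),
    variable_spec("cereal_type", "nominal",
                  levels = c("bran", "biscuit", "oat", "muesli", "sugary"),
                  reference_level = "bran",
                  cox_encoding = "dummy_set", ann_encoding = "one_hot",
                  gen_params = c(0.15, 0.25, 0.20, 0.15, 0.25)),
    variable_spec("processed_meat", "ordinal", levels = freq6,
                  reference_level = "never",
                  cox_encoding = "dummy_set", ann_encoding = "top_category",
                  gen_params = c(0.10, 0.30, 0.25, 0.25, 0.07, 0.03)),
    variable_spec("beef_intake", "ordinal", levels = freq6,
                  reference_level = "never",
                  cox_encoding = "dummy_set", ann_encoding = "top_category",
                  gen_params = c(0.15, 0.35, 0.25, 0.18, 0.05, 0.02)),
    variable_spec("age", "continuous",
                  cox_encoding = "continuous", ann_encoding = "minmax_continuous",
                  gen_params = c(40, 70)),
    variable_spec("bmi", "continuous",
                  cox_encoding = "continuous", ann_encoding = "minmax_continuous",
                  gen_params = c(18.5, 50))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Lehmer-style seed scrambling in double precision: derived streams stay
# decoupled and inside 32-bit range for any integer-valued input seed
scramble_seed <- function(seed, salt = 0) {
  as.integer((as.numeric(seed) * 48271 + 11 + as.numeric(salt) * 7919) %%
               2147483647)
}

is_schema <- function(x) {
  is.list(x) && length(x) > 0 &&
    all(vapply(x, inherits, TRUE, "variable_spec"))
}

stopifnot_schema <- function(schema) {
  if (!is_schema(schema)) stop("`schema` must be a list of variable_spec objects")
  invisible(schema)
}

#' Cox design-matrix term names for a schema
#'
#' Non-reference indicator terms are named `<variable>.<level>`; binary,
#' ordinal-numeric and continuous variables contribute a single term named
#' after the variable.
#'
#' @param schema List of [variable_spec()] objects.
#' @return Character vector of term names in schema order.
#' @export
cox_term_names <- function(schema) {
  stopifnot_schema(schema)
  unlist(lapply(schema, function(sp) {
    switch(sp$cox_encoding,
      binary_indicator = ,
      ordinal_numeric = ,
      continuous = sp$name,
      dummy_set = paste(sp$name, setdiff(sp$levels, sp$reference_level),
                        sep = "."),
      stop("unknown cox_encoding: ", sp$cox_encoding))
  }), use.names = FALSE)
}

#' Expand a cohort covariate table into a Cox design matrix
#'
#' Dummy-codes categorical variables against their reference level, maps
#' ordinal-numeric variables to 0-based integer scores, and passes binary
#' and continuous variables through.
#'
#' @param tab Data frame of covariates (one column per schema variable).
#' @param schema List of [variable_spec()] objects.
#' @return Numeric matrix with columns named per [cox_term_names()].
#' @export
cox_design_matrix <- function(tab, schema) {
  stopifnot_schema(schema)
  cols <- lapply(schema, function(sp) {
    v <- tab[[sp$name]]
    if (is.null(v)) stop("column '", sp$name, "' missing from table")
    switch(sp$cox_encoding,
      binary_indicator = {
        m <- matrix(as.numeric(as.character(v)), ncol = 1)
        colnames(m) <- sp$name
        m
      },
      ordinal_numeric = {
        m <- matrix(as.numeric(match(as.character(v), sp$levels)) - 1, ncol = 1)
        colnames(m) <- sp$name
        m
      },
      continuous = {
        m <- matrix(as.numeric(v), ncol = 1)
        colnames(m) <- sp$name
        m
      },
      dummy_set = {
        lv <- setdiff(sp$levels, sp$reference_level)
        m <- vapply(lv, function(l) as.numeric(as.character(v) == l),
                    numeric(length(v)))
        m <- matrix(m, ncol = length(lv))
        colnames(m) <- paste(sp$name, lv, sep = ".")
        m
      })
  })
  do.call(cbind, cols)
}

#' Serialize / deserialize a schema as JSON
#'
#' @param schema List of [variable_spec()] objects.
#' @param path File path of the JSON sidecar.
#' @return `write_schema_json()` returns `path` invisibly;
#'   `read_schema_json()` returns the schema list.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot_schema(schema)
  x <- lapply(schema, function(sp) {
    gp <- sp$gen_params
    list(name = sp$name, scale = sp$scale, levels = sp$levels,
         reference_level = sp$reference_level,
         cox_encoding = sp$cox_encoding, ann_encoding = sp$ann_encoding,
         gen_params = as.numeric(gp), gen_param_names = names(gp))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  specs <- lapply(x, function(e) {
    gp <- as.numeric(e$gen_params)
    if (!is.null(e$gen_param_names)) names(gp) <- unlist(e$gen_param_names)
    variable_spec(e$name, e$scale, levels = unlist(e$levels),
                  reference_level = e$reference_level,
                  cox_encoding = e$cox_encoding, ann_encoding = e$ann_encoding,
                  gen_params = gp)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
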