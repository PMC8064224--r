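# Shared fixtures built in code.

# A thickness map with given constant value (or full matrix), standardized.
make_map <- function(values = 100, layer = "TRT", eye = "OD",
                     orientation = "standardized", valid = NULL,
                     group = "WT", age_months = 1, subject = "fix-001") {
  if (length(values) == 1L) values <- matrix(values, 512, 512)
  retnorm:::new_thickness_map(layer, values,
                              list(eye = eye, group = group,
                                   age_months = age_months, subject = subject),
                              valid = valid, orientation = orientation)
}

# A block_grid built directly from a 3x3 matrix of means (all retained
# unless masked), for statistics tests that do not need full maps.
make_grid <- function(means, retained = NULL, layer = "TRT", eye = "OD",
                      group = "WT", age_months = 1, subject = "fix-001") {
  means <- matrix(means, 3, 3)
  if (is.null(retained)) retained <- !is.na(means)
  means[!retained] <- NA_real_
  structure(list(block_means = means,
                 valid_counts = matrix(ifelse(retained, 28900L, 0L), 3, 3),
                 block_valid = retained,
                 layer = layer, eye = eye, group = group,
                 age_months = age_months, subject = subject),
            class = "block_grid")
}

# A small in-memory normative database from a data.frame.
make_db <- function(df) retnorm:::new_normative_db(df, provenance = "built")

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
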