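#' Construct a multi-environment-trial dataset
#'
#' A `met_dataset` is a tibble of replicated trial observations in long
#' format — one row per (genotype, environment, replicate, trait) — carrying
#' ordered label indexes as attributes. It is the canonical in-memory form
#' for every analysis in the package. Labels are matched case-sensitively
#' after stripping leading/trailing whitespace; index order is the order of
#' first appearance in the data.
#'
#' @param data A data frame with columns `genotype`, `environment`,
#'   `replicate`, `trait` (labels) and `value` (numeric).
#' @return A tibble of class `met_dataset` with attributes
#'   `genotype_index`, `environment_index`, `replicate_index`, `trait_index`.
#' @examples
#' d <- tibble::tibble(
#'   genotype = rep(c("G1", "G2"), each = 3),
#'   environment = "E1", replicate = rep(c("R1", "R2", "R3"), 2),
#'   trait = "yield", value = c(1, 2, 3, 2, 3, 4)
#' )
#' met <- met_dataset(d)
#' n_genotypes(met)
#' @export
met_dataset <- function(data) {
  required <- c("genotype", "environment", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "metstab_config_error"
    )
  }
  data <- as_tibble(data)[required]
  for (col in c("genotype", "environment", "replicate", "trait")) {
    data[[col]] <- trimws(as.character(data[[col]]))
  }
  if (!is.numeric(data$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(data$value))))[1]
    abort(
      sprintf("column `value` is not numeric (first bad row: %d)", bad),
      class = "metstab_parse_error"
    )
  }
  key <- paste(data$genotype, data$environment, data$replicate, data$trait,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- data[dup[1], ]
    abort(
      sprintf(
        "duplicate observation key: genotype=%s, environment=%s, replicate=%s, trait=%s",
        first$genotype, first$environment, first$replicate, first$trait
      ),
      class = "metstab_validation_error"
    )
  }
  structure(
    data,
    genotype_index = unique(data$genotype),
    environment_index = unique(data$environment),
    replicate_index = unique(data$replicate),
    trait_index = unique(data$trait),
    class = c("met_dataset", class(data))
  )
}

as_met_dataset <- function(data) {
  if (inherits(data, "met_dataset")) data else met_dataset(data)
}

#' @rdname met_dataset
#' @param x A `met_dataset`.
#' @export
n_genotypes <- function(x) length(attr(as_met_dataset(x), "genotype_index"))

#' @rdname met_dataset
#' @export
n_environments <- function(x) length(attr(as_met_dataset(x), "environment_index"))

#' @rdname met_dataset
#' @export
n_traits <- function(x) length(attr(as_met_dataset(x), "trait_index"))

#' Is the trial a complete balanced design?
#'
#' Reports `TRUE` iff every genotype x environment x replicate x trait cell
#' is present exactly once.
#'
#' @param data A `met_dataset` or compatible data frame.
#' @return Logical scalar.
#' @export
is_balanced <- function(data) {
  data <- as_met_dataset(data)
  expected <- length(attr(data, "genotype_index")) *
    length(attr(data, "environment_index")) *
    length(attr(data, "replicate_index")) *
    length(attr(data, "trait_index"))
  nrow(data) == expected
}

#' @exportS3Method base::print
print.met_dataset <- function(x, ...) {
  cat(sprintf(
    "<met_dataset> %d observations: %d genotypes x %d environments x %d replicates x %d traits%s\n",
    nrow(x), n_genotypes(x), n_environments(x),
    length(attr(x, "replicate_index")), n_traits(x),
    if (is_balanced(x)) " (balanced)" else ""
  ))
  NextMethod()
}

#' Read a long-format trial table from delimited text
#'
#' Reads an RFC-4180 CSV (or other delimited file) with one row per
#' replicated observation and returns a validated [met_dataset()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   (`genotype`, `environment`, `replicate`, `trait`, `value`) to the
#'   column names used in the file. Canonical names absent from the map are
#'   assumed to be present verbatim.
#' @param delim Field delimiter, default `","`.
#' @return A [met_dataset()].
#' @export
read_met_long <- function(path, column_map = NULL, delim = ",") {
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  map <- c(
    genotype = "genotype", environment = "environment",
    replicate = "replicate", trait = "trait", value = "value"
  )
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown)) {
      abort(sprintf("column_map has unknown key(s): %s",
                    paste(unknown, collapse = ", ")),
            class = "metstab_config_error")
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("input file lacks mapped column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metstab_config_error")
  }
  out <- tibble(
    genotype = raw[[map[["genotype"]]]],
    environment = raw[[map[["environment"]]]],
    replicate = raw[[map[["replicate"]]]],
    trait = raw[[map[["trait"]]]],
    value = raw[[map[["value"]]]]
  )
  num <- suppressWarnings(as.numeric(out$value))
  bad <- which(is.na(num) & !is.na(out$value))
  if (length(bad)) {
    abort(sprintf("non-numeric value %s at data row %d",
                  deparse(out$value[bad[1]]), bad[1]),
          class = "metstab_parse_error")
  }
  out$value <- num
  met_dataset(out)
}

#' Write a trial dataset as long-format CSV
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_met_long <- function(data, path) {
  data <- as_met_dataset(data)
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Genotype-by-environment cell-mean matrix
#'
#' Averages replicates per (genotype, environment) cell for one trait,
#' producing the `ge_matrix` consumed by [fit_ammi()] and [fit_gge()].
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param trait Trait label; may be omitted when the dataset holds a single
#'   trait.
#' @return A `ge_matrix`: numeric genotype x environment matrix with
#'   attributes `trait` and `n_rep` (the minimum replicate count per cell).
#' @examples
#' truth <- random_truth(G = 5, E = 4, k = 1, seed = 1)
#' cm <- cell_means(simulate_trait(truth))
#' dim(cm)
#' @export
cell_means <- function(data, trait = NULL) {
  data <- as_met_dataset(data)
  traits <- attr(data, "trait_index")
  if (is.null(trait)) {
    if (length(traits) != 1L) {
      abort("dataset holds several traits; supply `trait`")
    }
    trait <- traits
  }
  if (!trait %in% traits) {
    abort(sprintf("trait %s not present in dataset", deparse(trait)))
  }
  gen <- attr(data, "genotype_index")
  env <- attr(data, "environment_index")
  sub <- dplyr::filter(as_tibble(data), .data$trait == !!trait)
  cells <- sub |>
    dplyr::group_by(.data$genotype, .data$environment) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  full <- tidyr::expand_grid(genotype = gen, environment = env)
  joined <- dplyr::left_join(full, cells, by = c("genotype", "environment"))
  empty <- which(is.na(joined$mean))
  if (length(empty)) {
    abort(sprintf("empty cell: genotype=%s, environment=%s",
                  joined$genotype[empty[1]], joined$environment[empty[1]]),
          class = "metstab_validation_error")
  }
  m <- matrix(joined$mean, nrow = length(gen), ncol = length(env),
              byrow = TRUE, dimnames = list(gen, env))
  ge_matrix(m, trait = trait, n_rep = min(joined$n))
}

#' @rdname cell_means
#' @param values Numeric genotype x environment matrix with dimnames.
#' @param n_rep Replicates per cell used to form the means.
#' @export
ge_matrix <- function(values, trait = "trait", n_rep = 1L) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    abort("ge_matrix must be complete (no missing cells)",
          class = "metstab_validation_error")
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("ge_matrix needs at least 2 genotypes and 2 environments",
          class = "metstab_validation_error")
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("E", seq_len(ncol(values)))
  structure(values, trait = trait, n_rep = as.integer(n_rep),
            class = c("ge_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.ge_matrix <- function(x, ...) {
  cat(sprintf("<ge_matrix> trait %s: %d genotypes x %d environments (n_rep = %d)\n",
              deparse(attr(x, "trait")), nrow(x), ncol(x), attr(x, "n_rep")))
  print(unclass(x)[,])
  invisible(x)
}

#' @export
tidy.ge_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x)[,], responseName = "mean",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(genotype = "Var1", environment = "Var2") |>
    dplyr::mutate(trait = attr(x, "trait"), .before = 1)
}
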