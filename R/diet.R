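# In silico diet presets: maximum community uptake rates of dietary
# metabolites, in mmol/day.

#' Generate a diet specification
#'
#' Three structural presets are provided, emulating an average European
#' diet (`EUD`), a high protein diet (`HPD`, amino-acid bounds raised) and
#' a high fiber diet (`HFD`, fiber/polysaccharide bounds raised and the
#' L-cysteine bound set to 1.84 times its EUD value). The numeric bounds
#' are package choices on the toy metabolite universe; the presets encode
#' the published relative structure, notably the HFD/EUD L-cysteine ratio
#' of 1.84 (84% more).
#'
#' @param preset one of `"EUD"`, `"HPD"`, `"HFD"`.
#' @param scale non-negative scalar multiplying every bound (`0` gives a
#'   starvation control).
#' @return A `diet_spec`: list with `name` and `bounds` (named numeric,
#'   mmol/day).
#' @examples
#' gen_diet("HFD")$bounds[["cys_L"]] / gen_diet("EUD")$bounds[["cys_L"]]
#' @export
gen_diet <- function(preset = c("EUD", "HPD", "HFD"), scale = 1) {
  preset <- match.arg(preset)
  stopifnot(is.numeric(scale), scale >= 0)
  eud <- c(fiber = 6, glc = 30, ac = 5,
           ala_L = 8, ala_D = 3, ser_L = 10, cys_L = 6, met_L = 2,
           val_L = 40, leu_L = 48,
           so4 = 30, nh3 = 140, h2o = 10000)
  aa <- c("ala_L", "ala_D", "ser_L", "cys_L", "met_L", "val_L", "leu_L")
  bounds <- switch(preset,
    EUD = eud,
    HPD = { d <- eud; d[aa] <- d[aa] * 2.5; d },
    HFD = {
      d <- eud
      d["fiber"] <- d["fiber"] * 3
      d["glc"] <- d["glc"] * 0.75
      d["cys_L"] <- d["cys_L"] * 1.84
      d
    })
  structure(list(name = preset, bounds = bounds * scale),
            class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("<diet_spec> ", x$name, ": ", length(x$bounds),
      " dietary metabolites, total ", sum(x$bounds), " mmol/day\n", sep = "")
  invisible(x)
}

#' Write / read a diet as TSV
#'
#' Columns `metabolite_id`, `max_uptake_mmol_per_day`.
#'
#' @param diet a `diet_spec`.
#' @param path file path.
#' @return `read_diet` returns a `diet_spec`; `write_diet` its path,
#'   invisibly.
#' @export
write_diet <- function(diet, path) {
  stopifnot(inherits(diet, "diet_spec"))
  df <- data.frame(metabolite_id = names(diet$bounds),
                   max_uptake_mmol_per_day = as.numeric(diet$bounds))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diet
#' @param name diet label for the object read back.
#' @export
read_diet <- function(path, name = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "max_uptake_mmol_per_day") %in% names(df)))
  b <- setNames(df$max_uptake_mmol_per_day, df$metabolite_id)
  if (any(!is.finite(b)) || any(b < 0))
    stop("diet bounds must be finite and non-negative")
  structure(list(name = name, bounds = b), class = "diet_spec")
}
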