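#' The standard environmental variable set
#'
#' The 20 predictors used throughout the pipeline: altitude plus the 19
#' bioclim layers, in the WorldClim v1.4 convention (temperatures in
#' degrees C x 10, precipitation in mm). Units are metadata only; no
#' conversion is performed anywhere in the package.
#'
#' @return An object of class `env_variable_set`: a character vector of the
#'   20 variable names with a `units` attribute (named character vector).
#' @examples
#' env_variable_set()
#' @export
env_variable_set <- function() {
  names <- c("alt", paste0("bio", 1:19))
  temp <- paste0("bio", c(1, 2, 5, 6, 7, 8, 9, 10, 11))
  prec <- paste0("bio", c(12, 13, 14, 16, 17, 18, 19))
  units <- setNames(rep("index", 20L), names)
  units["alt"] <- "m"
  units[temp] <- "degC x 10"
  units[prec] <- "mm"
  units["bio4"] <- "sd x 100"
  structure(names, units = units, class = "env_variable_set")
}

#' @export
print.env_variable_set <- function(x, ...) {
  cat("Environmental variable set:", length(x), "variables\n")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

# internal: assert a data frame carries the full env column set
check_env_columns <- function(df, env_set = env_variable_set()) {
  missing <- setdiff(unclass(env_set), names(df))
  if (length(missing)) {
    stop("missing environmental column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
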