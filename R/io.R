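#' Serialize and restore fuzzy models as JSON
#'
#' The JSON document is schema-versioned and self-contained: species
#' annotations, transitions and active gates with transfer parameters.
#'
#' @param model a \linkS4class{FuzzyModel}.
#' @param path output (input) file path.
#' @return \code{writeModelJSON}: invisibly, \code{path};
#'   \code{readModelJSON}: a \linkS4class{FuzzyModel}.
#' @export
writeModelJSON <- function(model, path) {
    doc <- list(
        schema = "fuzzyhep-model/1",
        species = model@network@species,
        transitions = model@network@transitions,
        gates = lapply(model@gates, function(g)
            list(target = g$target, sources = as.list(g$sources),
                 signs = as.list(g$signs), kind = g$kind,
                 k = g$k, n = g$n)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    if (!identical(doc$schema, "fuzzyhep-model/1"))
        stop("unsupported model schema: ", doc$schema)
    net <- PriorNetwork(doc$species, doc$transitions)
    gl <- unname(apply(doc$gates, 1L, function(row) {
        list(target = row$target, sources = unlist(row$sources),
             signs = as.integer(unlist(row$signs)), kind = row$kind,
             k = as.numeric(row$k), n = as.numeric(row$n))
    }))
    new("FuzzyModel", network = net, gates = gl)
}

#' Read and write experiment designs as CSV
#'
#' Columns: \code{condition}, \code{stimuli}
#' (\code{species=level} pairs separated by \code{;}, empty for none) and
#' \code{inhibited} (species separated by \code{;}).
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param path file path.
#' @return \code{readDesignCSV}: an \linkS4class{ExperimentDesign}.
#' @export
writeDesignCSV <- function(design, path) {
    df <- data.frame(
        condition = design@conditions,
        stimuli = vapply(design@stimuli, function(st)
            paste(names(st), st, sep = "=", collapse = ";"), character(1)),
        inhibited = vapply(design@inhibited, paste, character(1),
                           collapse = ";"),
        stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(path) {
    df <- read.table(path, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE,
                     colClasses = "character")
    stimuli <- lapply(df$stimuli, function(s) {
        if (!nzchar(s)) return(numeric())
        parts <- strsplit(strsplit(s, ";")[[1L]], "=")
        setNames(vapply(parts, function(p) as.numeric(p[2L]), numeric(1)),
                 vapply(parts, `[`, character(1), 1L))
    })
    inhibited <- lapply(df$inhibited, function(s)
        if (nzchar(s)) strsplit(s, ";")[[1L]] else character())
    ExperimentDesign(df$condition, stimuli, inhibited)
}
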