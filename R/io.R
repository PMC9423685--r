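#' Read binary descriptor views from delimited files
#'
#' One file per feature view: first column the drug identifier, remaining
#' columns 0/1 descriptor bits. All views must list the same drugs in the
#' same order. The delimiter is sniffed from the extension (`.tsv` = tab,
#' otherwise comma).
#'
#' @param paths character vector of file paths; names become view names.
#' @return named list of binary matrices with drug ids as rownames.
#' @export
readDescriptorViews <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  views <- lapply(paths, function(p) {
    sep <- if (grepl("\\.tsv$", p)) "\t" else ","
    df <- utils::read.table(p, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  })
  ids <- rownames(views[[1]])
  for (v in seq_along(views))
    if (!identical(rownames(views[[v]]), ids))
      stop("view '", names(views)[v],
           "' lists different drugs (or a different order) than view '",
           names(views)[1], "'")
  views
}

#' Read a labeled interaction table
#'
#' Delimited text with columns `drug_a`, `drug_b`, `event_class`
#' (1-based class labels on disk). Identifiers are mapped to indices in
#' `drugIds`; pairs are canonicalized to `i < j`.
#'
#' @param path file path (comma- or tab-delimited by extension).
#' @param drugIds ordered drug identifiers of the descriptor views.
#' @return `data.frame` with integer columns `i`, `j`, `class`.
#' @export
readInteractions <- function(path, drugIds) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("drug_a", "drug_b", "event_class")
  if (!all(need %in% names(df)))
    stop("interaction file needs columns: ", paste(need, collapse = ", "))
  i <- match(as.character(df$drug_a), drugIds)
  j <- match(as.character(df$drug_b), drugIds)
  if (anyNA(i) || anyNA(j))
    stop("interaction file references unknown drug identifier(s): ",
         paste(utils::head(unique(c(df$drug_a[is.na(i)],
                                    df$drug_b[is.na(j)])), 5),
               collapse = ", "))
  canonicalizePairs(data.frame(i = i, j = j,
                               class = as.integer(df$event_class)),
                    length(drugIds))
}

#' Write a synthetic dataset to disk
#'
#' Writes one descriptor CSV per view (`<view>.csv`), the interaction
#' table (`interactions.csv`), and the ground truth (communities, class
#' config) as JSON — exactly the formats [readDescriptorViews()] and
#' [readInteractions()] consume.
#'
#' @param dataset a [DDIDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeDDIData <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  ids <- drugIds(dataset)
  for (v in names(featureViews(dataset))) {
    m <- featureViews(dataset)[[v]]
    df <- data.frame(drug_id = ids, m, check.names = FALSE)
    f <- file.path(dir, paste0(v, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  ev <- eventTable(dataset)
  intf <- file.path(dir, "interactions.csv")
  utils::write.csv(data.frame(drug_a = ids[ev$i], drug_b = ids[ev$j],
                              event_class = ev$class),
                   intf, row.names = FALSE, quote = FALSE)
  files <- c(files, intf)
  truth <- list(drug_ids = ids, n_classes = dataset@nClasses)
  if (length(communities(dataset)))
    truth$communities <- communities(dataset)
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, tf))
}

#' Load a dataset from descriptor and interaction files
#'
#' @param viewPaths named character vector of descriptor files.
#' @param interactionPath interaction table file.
#' @param nClasses number of event classes (default: max observed).
#' @return a [DDIDataset-class].
#' @export
readDDIData <- function(viewPaths, interactionPath, nClasses = NULL) {
  views <- readDescriptorViews(viewPaths)
  ids <- rownames(views[[1]])
  events <- readInteractions(interactionPath, ids)
  DDIDataset(views = views, events = events, nClasses = nClasses,
             drugIds = ids)
}
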