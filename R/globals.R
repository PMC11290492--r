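## data.table non-standard-evaluation column names
utils::globalVariables(c("rc", "kmer", "pos0", "q", "chrom", "read",
                         "dir", "diag", ":="))

#' @importFrom data.table data.table :=
NULL

.datatable.aware <- TRUE
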