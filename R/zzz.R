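#' @keywords internal
#' @importFrom data.table := .N .SD data.table as.data.table rbindlist fread fwrite
#' @importFrom methods is
#' @importFrom stats setNames
"_PACKAGE"

.datatable.aware <- TRUE
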