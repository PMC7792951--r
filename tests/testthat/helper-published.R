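# Published utilization-model estimates (coefficient, odds ratio) for formal
# and informal care, used as inputs for the exp(beta) identity checks.
published_or_table <- function() {
  read.table(header = TRUE, text = "
outcome term coef or
formal female 0.3556 1.4270
formal age_66_80 0.5817 1.7890
formal age_80p 1.7870 5.9716
formal single 0.6815 1.9768
formal educ_secondary -0.0919 0.9122
formal educ_tertiary 0.1363 1.1460
formal nchild 0.0028 1.0028
formal chhh -0.2824 0.7540
formal hhsize -0.1669 0.8463
formal urban 0.2344 1.2642
formal saghs -0.7566 0.4693
formal adl 0.4994 1.6477
formal ncd 0.1347 1.1441
formal southern -1.2364 0.2904
formal eastern -0.6313 0.5319
formal northern -0.8903 0.4105
formal constant -2.8983 0.0551
informal female 0.1415 1.1520
informal age_66_80 0.0423 1.0432
informal age_80p 0.7107 2.0354
informal single 0.5967 1.8161
informal educ_secondary 0.0244 1.0247
informal educ_tertiary -0.0372 0.9635
informal nchild 0.0836 1.0872
informal chhh -0.3232 0.7238
informal hhsize -0.1995 0.8192
informal urban -0.2925 0.7464
informal saghs -0.5225 0.5931
informal adl 0.4329 1.5417
informal ncd 0.1663 1.1810
informal southern -0.5970 0.5505
informal eastern 0.2249 1.2521
informal northern 0.7492 2.1154
informal constant -1.1377 0.3206
", stringsAsFactors = FALSE)
}
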