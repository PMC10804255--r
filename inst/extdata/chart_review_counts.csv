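table,stratum,n_pairs,n_distinct
setting,nonED_nonED,542,14
setting,ED_nonED,176,10
setting,nonED_ED,23,22
setting,ED_ED,274,134
setting,overall,1015,180
method,same_method,766,128
method,different_method,249,52
method,overall,1015,180
interval,1-7,797,31
interval,8-14,48,19
interval,15-21,31,17
interval,22-28,20,14
interval,29-35,17,10
interval,36-42,17,15
interval,43-49,10,8
interval,50-56,18,14
interval,57-63,5,3
interval,64-70,7,6
interval,71-77,2,2
interval,78-84,9,9
interval,85-91,6,6
interval,92+,28,26
interval,overall,1015,180
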