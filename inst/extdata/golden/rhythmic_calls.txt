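P0004
P0006
P0007
P0012
P0015
P0016
P0018
P0019
P0020
P0022
P0025
P0026
P0027
P0028
P0029
P0030
P0031
P0035
P0036
P0037
P0038
P0039
P0040
P0041
P0043
P0047
P0049
P0050
P0051
P0052
P0054
P0055
P0057
P0058
P0059
P0061
P0062
P0064
P0065
P0066
P0067
P0068
P0069
P0071
P0073
P0075
P0076
P0080
P0081
P0082
P0085
P0086
P0088
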