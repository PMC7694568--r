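"","suaeda","phragmites","mudflat"
"suaeda",0.8789,0.1128,0.0083
"phragmites",0.0183,0.9802,0.0015
"mudflat",0.0598,0.0031,0.9370
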