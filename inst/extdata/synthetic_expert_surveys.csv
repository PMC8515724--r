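expert_id,profession,source,target
E01,physician,Age,LS
E01,physician,Age,SS
E01,physician,Age,TP
E01,physician,EG,SS
E01,physician,EG,TP
E01,physician,ES,SS
E01,physician,ES,TP
E01,physician,LS,ES
E01,physician,MF,TP
E01,physician,TP,SS
E02,physician,Age,TP
E02,physician,EG,TP
E02,physician,ES,LS
E02,physician,ES,SS
E02,physician,ES,TP
E02,physician,MF,TP
E02,physician,TP,SS
E03,physician,Age,TP
E03,physician,ES,LS
E03,physician,ES,TP
E03,physician,MF,TP
E03,physician,TP,SS
E04,nurse,Age,LS
E04,nurse,Age,SS
E04,nurse,Age,TP
E04,nurse,EG,SS
E04,nurse,ES,SS
E04,nurse,ES,TP
E04,nurse,MF,TP
E04,nurse,SS,LS
E04,nurse,TP,SS
E05,nurse,Age,TP
E05,nurse,EG,SS
E05,nurse,ES,LS
E05,nurse,ES,SS
E05,nurse,ES,TP
E05,nurse,MF,TP
E05,nurse,SS,LS
E05,nurse,SS,TP
E05,nurse,TP,SS
E06,nurse,Age,SS
E06,nurse,Age,TP
E06,nurse,EG,SS
E06,nurse,ES,SS
E06,nurse,LS,ES
E06,nurse,MF,TP
E06,nurse,SS,LS
E06,nurse,SS,TP
E06,nurse,TP,SS
E07,psychologist,Age,TP
E07,psychologist,EG,TP
E07,psychologist,ES,LS
E07,psychologist,ES,SS
E07,psychologist,ES,TP
E07,psychologist,MF,TP
E07,psychologist,SS,TP
E07,psychologist,TP,SS
E08,psychologist,Age,SS
E08,psychologist,EG,TP
E08,psychologist,ES,LS
E08,psychologist,ES,SS
E08,psychologist,ES,TP
E08,psychologist,MF,TP
E08,psychologist,SS,LS
E08,psychologist,TP,SS
E09,psychologist,Age,LS
E09,psychologist,Age,SS
E09,psychologist,Age,TP
E09,psychologist,EG,SS
E09,psychologist,EG,TP
E09,psychologist,ES,LS
E09,psychologist,ES,TP
E09,psychologist,MF,TP
E09,psychologist,TP,SS
E10,psychologist,Age,LS
E10,psychologist,Age,SS
E10,psychologist,EG,TP
E10,psychologist,MF,SS
E10,psychologist,MF,TP
E10,psychologist,TP,SS
E11,teacher,Age,SS
E11,teacher,Age,TP
E11,teacher,EG,SS
E11,teacher,ES,LS
E11,teacher,ES,SS
E11,teacher,ES,TP
E11,teacher,MF,TP
E11,teacher,SS,LS
E11,teacher,TP,SS
E12,teacher,Age,LS
E12,teacher,Age,SS
E12,teacher,Age,TP
E12,teacher,EG,SS
E12,teacher,EG,TP
E12,teacher,ES,LS
E12,teacher,ES,SS
E12,teacher,ES,TP
E12,teacher,MF,TP
E12,teacher,SS,TP
E12,teacher,TP,SS
E13,pedagogue,Age,LS
E13,pedagogue,Age,SS
E13,pedagogue,Age,TP
E13,pedagogue,EG,TP
E13,pedagogue,ES,LS
E13,pedagogue,ES,SS
E13,pedagogue,LS,ES
E13,pedagogue,MF,SS
E13,pedagogue,MF,TP
E13,pedagogue,TP,SS
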