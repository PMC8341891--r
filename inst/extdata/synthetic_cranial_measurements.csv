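specimen_id,feature,value_mm,distorted
SYN-001,skull_length,368.3,0
SYN-002,skull_length,302.2,0
SYN-002,snout_length,69.4,0
SYN-003,skull_length,285,0
SYN-003,snout_length,84.6,1
SYN-004,skull_length,314.7,0
SYN-004,snout_length,34.2,1
SYN-005,skull_length,228.2,0
SYN-005,snout_length,53.1,0
SYN-006,skull_length,219.2,0
SYN-006,snout_length,63.1,0
SYN-007,skull_length,199.1,0
SYN-007,snout_length,48.2,0
SYN-008,skull_length,163.4,0
SYN-008,snout_length,36,0
SYN-009,skull_length,142,0
SYN-009,snout_length,26.4,1
SYN-010,skull_length,135.9,0
SYN-010,snout_length,35.3,0
SYN-011,skull_length,188.3,0
SYN-011,snout_length,45.2,1
SYN-012,skull_length,145.7,0
SYN-012,snout_length,50.8,1
SYN-013,skull_length,270.8,0
SYN-013,snout_length,48.7,1
SYN-014,skull_length,397.2,0
SYN-014,snout_length,116.9,0
SYN-015,skull_length,247.8,0
SYN-015,snout_length,61.2,1
SYN-016,skull_length,204.7,0
SYN-016,snout_length,51.9,1
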