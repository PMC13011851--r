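raw_name,code
zusanli,ST36
zu sanli,ST36
zhongwan,CV12
neiguan,PC6
taichong,LR3
tianshu,ST25
gongsun,SP4
pishu,BL20
weishu,BL21
neiting,ST44
liangqiu,ST34
yinlingquan,SP9
hegu,LI4
taixi,KI3
danzhong,CV17
shanzhong,CV17
tanzhong,CV17
fenglong,ST40
baihui,GV20
qihai,CV6
sanyinjiao,SP6
qimen,LR14
guanyuan,CV4
shangwan,CV13
ganshu,BL18
yanglingquan,GB34
chongyang,ST42
liangmen,ST21
jianli,CV11
zulinqi,GB41
xiawan,CV10
shenmen,HT7
taiyi,ST23
taibai,SP3
sibai,ST2
geshu,BL17
shangjuxu,ST37
zhangmen,LR13
taiyang,EX-HN5
shenmai,BL62
zhaohai,KI6
xinshu,BL15
jianwaishu,SI14
jianjing,GB21
xingjian,LR2
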